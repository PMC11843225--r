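#' Task weights and subsets for the intelligence composites
#'
#' Factor-analysis loadings used as g-factor weights for the ten cognitive
#' tasks, plus the task subsets defining the crystallized (2 tasks) and fluid
#' (5 tasks) composites.
#'
#' @return List with `weights` (named numeric, all strictly positive),
#'   `fluid` and `crystallized` (character vectors of task names, disjoint).
#' @export
g_factor_weights <- function() {
  w <- c(pic_vocab    = 0.624,
         oral_reading = 0.642,
         card_sort    = 0.364,
         flanker      = 0.259,
         list_sort    = 0.451,
         matrices     = 0.626,
         pic_seq      = 0.354,
         pattern_comp = 0.232,
         line_orient  = 0.578,
         word_mem     = 0.294)
  list(weights = w,
       fluid = c("card_sort", "flanker", "list_sort", "matrices", "pic_seq"),
       crystallized = c("pic_vocab", "oral_reading"))
}

.zscore_tasks <- function(table, tasks) {
  miss <- setdiff(tasks, names(table))
  if (length(miss))
    stop("missing task column(s): ", paste(miss, collapse = ", "))
  z <- vapply(tasks, function(tk) {
    x <- table[[tk]]
    if (anyNA(x)) stop("missing values in task column ", tk)
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }, numeric(nrow(table)))
  matrix(z, nrow = nrow(table), dimnames = list(NULL, tasks))
}

#' Intelligence composite scores
#'
#' Tasks are z-scored across subjects, then: crystallized (CI) and fluid (FI)
#' intelligence are the unweighted means of their task subsets; general
#' intelligence (G) is the loading-weighted mean of all ten z-scored tasks,
#' `sum(w_i * z_i) / sum(w_i)`.
#'
#' @param table Behavioral data.frame with the task columns.
#' @param which One of `"CI"`, `"FI"`, `"G"`.
#' @param weights Weight specification as returned by [g_factor_weights()].
#' @return Numeric vector, one score per subject.
#' @export
composite_score <- function(table, which = c("G", "FI", "CI"),
                            weights = g_factor_weights()) {
  which <- match.arg(which)
  if (which == "CI") {
    z <- .zscore_tasks(table, weights$crystallized)
    return(rowMeans(z))
  }
  if (which == "FI") {
    z <- .zscore_tasks(table, weights$fluid)
    return(rowMeans(z))
  }
  w <- weights$weights
  z <- .zscore_tasks(table, names(w))
  as.numeric(z %*% w) / sum(w)
}

#' Regress confounds out of one or more columns
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' covariate columns. The covariate matrix must be full rank after adding
#' the intercept; collinear columns are named in the error. Residuals are
#' orthogonal to every covariate column.
#'
#' @param values Numeric vector or matrix (columns residualized jointly).
#' @param covariates Numeric matrix or data.frame of confounds (age, sex,
#'   handedness, education, framewise displacement, ...), one row per
#'   observation.
#' @return Residuals with the same shape as `values`.
#' @export
residualize_confounds <- function(values, covariates) {
  vec_in <- is.null(dim(values))
  y <- as.matrix(values)
  x <- as.matrix(covariates)
  if (!is.numeric(x)) stop("covariates must be numeric; encode factors first")
  if (nrow(y) != nrow(x)) stop("values and covariates disagree in length")
  if (nrow(x) <= ncol(x) + 1) stop("need n > number of covariates + 1")
  design <- cbind(`(intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrd, y)
  if (vec_in) as.numeric(res) else res
}

#' Numeric covariate matrix from a behavioral table
#'
#' Encodes the standard confounds for regression: age and education in
#' years, sex as 0/1, handedness as a signed score, and mean framewise
#' displacement in mm.
#'
#' @param behavior Behavioral data.frame containing columns `age`, `sex`,
#'   `handedness`, `education`, `fd`.
#' @return Numeric matrix with those five columns.
#' @export
encode_covariates <- function(behavior) {
  need <- c("age", "sex", "handedness", "education", "fd")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  sex <- behavior$sex
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(factor(sex)) - 1L
  cbind(age = as.numeric(behavior$age), sex = as.numeric(sex),
        handedness = as.numeric(behavior$handedness),
        education = as.numeric(behavior$education),
        fd = as.numeric(behavior$fd))
}
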