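#' Average bilateral homolog cluster predictors
#'
#' When the left and right homologs of a cluster carry essentially the same
#' signal, keeping both as predictors is redundant. For each declared pair
#' whose across-subject Pearson correlation is at least `min_rho` on every
#' gradient axis, the two coordinate columns are replaced by their mean
#' (named `c<left>+<right>_g<k>`); otherwise both are kept and the decision
#' is recorded.
#'
#' @param table Subject x (cluster-axis) matrix from [cluster_coordinates()].
#' @param pairs List of length-2 vectors of cluster ids `(left, right)`.
#' @param min_rho Minimum per-axis correlation to merge (default 0.6).
#' @return The (possibly reduced) matrix, with attribute `pairing`: a
#'   data.frame recording each pair's minimum axis correlation and whether it
#'   was merged.
#' @export
bilateral_average <- function(table, pairs, min_rho = 0.6) {
  stopifnot(is.matrix(table))
  log <- data.frame(left = integer(0), right = integer(0),
                    min_axis_r = numeric(0), merged = logical(0))
  for (pr in pairs) {
    l <- pr[1]; r <- pr[2]
    if (l == r) stop("cannot pair a cluster with itself")
    lcols <- grep(sprintf("^c%d_g", l), colnames(table), value = TRUE)
    rcols <- grep(sprintf("^c%d_g", r), colnames(table), value = TRUE)
    if (length(lcols) == 0 || length(rcols) == 0 ||
        length(lcols) != length(rcols))
      stop("declared pair (", l, ", ", r, ") not present in the table")
    axes_r <- vapply(seq_along(lcols), function(i)
      stats::cor(table[, lcols[i]], table[, rcols[i]]), numeric(1))
    merged <- all(axes_r >= min_rho)
    log <- rbind(log, data.frame(left = l, right = r,
                                 min_axis_r = min(axes_r), merged = merged))
    if (merged) {
      avg <- (table[, lcols, drop = FALSE] + table[, rcols, drop = FALSE]) / 2
      colnames(avg) <- sub(sprintf("^c%d_", l), sprintf("c%d+%d_", l, r), lcols)
      keep <- setdiff(colnames(table), c(lcols, rcols))
      table <- cbind(table[, keep, drop = FALSE], avg)
    }
  }
  attr(table, "pairing") <- log
  table
}

#' Stratified fold assignment
#'
#' Subjects are ranked by the dependent variable, cut into `n_bins` quantile
#' bins, shuffled within each bin, and dealt round-robin to the k folds, so
#' fold sizes differ by at most one within every stratum and every fold sees
#' the full range of y.
#'
#' @param y Numeric dependent variable.
#' @param k Number of folds (>= 2).
#' @param n_bins Number of quantile strata (default `k`).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold indices in `0:(k-1)`, with attributes `k`,
#'   `n_bins`, `seed`.
#' @export
stratified_folds <- function(y, k, n_bins = k, seed = 1L) {
  n <- length(y)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("more folds than subjects")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ord <- order(y, sample.int(n))      # random tie-break
  bin <- floor((seq_len(n) - 1) * n_bins / n) + 1
  fold <- integer(n)
  counter <- 0L
  for (b in seq_len(n_bins)) {
    members <- ord[bin == b]
    members <- members[sample.int(length(members))]
    fold[members] <- (counter + seq_along(members) - 1L) %% k
    counter <- counter + length(members)
  }
  structure(fold, k = as.integer(k), n_bins = as.integer(n_bins),
            seed = as.integer(seed))
}

# shared fold machinery -------------------------------------------------------

# precompute everything reusable across permutations for one train/test split
.fold_precompute <- function(y, x1, train, test) {
  p <- ncol(x1) - 1L
  if (length(train) <= p + 1) stop("training fold too small: need n_train > p + 1")
  if (length(test) <= p + 1) stop("test fold too small: need n_test > p + 1")
  qr_tr <- qr(x1[train, , drop = FALSE])
  if (qr_tr$rank < ncol(x1)) stop("singular training design matrix")
  xte <- x1[test, , drop = FALSE]
  xtx <- crossprod(xte)
  if (any(diag(xtx) == 0) || inherits(try(ch <- chol(xtx), silent = TRUE), "try-error"))
    stop("singular test design matrix")
  yte <- y[test]
  list(qr_tr = qr_tr, ytr = y[train], xte = xte, yte = yte, p = p,
       n_test = length(test), sstot = sum((yte - mean(yte))^2),
       cinv_diag = diag(chol2inv(ch)))
}

# evaluate coefficient matrix B ((p+1) x m) on the precomputed test fold
.eval_beta <- function(b, pre) {
  b <- as.matrix(b)
  preds <- pre$xte %*% b
  ssr <- colSums((pre$yte - preds)^2)
  dfe <- pre$n_test - pre$p - 1
  r2 <- 1 - ssr / pre$sstot
  perfect <- ssr <= 1e-10 * max(pre$sstot, 1)
  f <- ifelse(perfect, Inf,
              ifelse(r2 <= 0, 0, (r2 / pre$p) / ((1 - r2) / dfe)))
  sigma2 <- ssr / dfe
  tmat <- b[-1, , drop = FALSE] /
    sqrt(outer(pre$cinv_diag[-1], sigma2))
  list(F = f, t = tmat, r2 = r2, sigma2 = sigma2)
}

#' Fit on a training set, evaluate out of sample
#'
#' Ordinary least squares (with intercept) on the training rows; the model is
#' then judged entirely on the held-out rows: out-of-sample
#' `R^2 = 1 - SS_res/SS_tot` with test-fold centering,
#' `F = (R^2/p) / ((1-R^2)/(n_test-p-1))` floored at 0 for negative R^2 and
#' reported as `Inf` when the test residuals vanish, and
#' `t_j = beta_j / sqrt(sigma2_test * [(X_test' X_test)^-1]_jj)` with
#' `sigma2_test = SS_res/(n_test-p-1)`.
#'
#' @param y Response vector.
#' @param x Predictor matrix (no intercept column).
#' @param train,test Disjoint row index vectors; both must exceed `p + 1`
#'   observations.
#' @return List with `beta` (intercept first), `F`, `t` (per predictor),
#'   `r2`.
#' @export
fold_fit_eval <- function(y, x, train, test) {
  x <- as.matrix(x)
  x1 <- cbind(`(intercept)` = 1, x)
  pre <- .fold_precompute(y, x1, train, test)
  beta <- qr.coef(pre$qr_tr, pre$ytr)
  ev <- .eval_beta(beta, pre)
  list(beta = beta, F = ev$F[1], t = stats::setNames(ev$t[, 1], colnames(x)),
       r2 = ev$r2[1])
}

# add-one permutation p-value; finite nulls only
.perm_p <- function(stat, null) {
  null <- null[is.finite(null)]
  (1 + sum(abs(null) >= abs(stat))) / (1 + length(null))
}

#' Cross-validated permutation inference for one association model
#'
#' For each fold, the model is fit on the remaining folds and its F and
#' per-predictor t statistics are evaluated out of sample on the held-out
#' fold; the real statistics are the fold averages. Null statistics mirror
#' that construction: for each of `n_perm` permutations the response is
#' permuted once, the model is refit on each fold's (permuted) training rows
#' and evaluated on the intact test fold, and the k fold statistics are
#' averaged, giving `n_perm` null values of the same fold-averaged statistic
#' (the `k * n_perm` per-fold values are also returned as the raw null
#' pool). Sharing one permutation across folds preserves the between-fold
#' correlation of the real statistic, which makes the test calibrated;
#' pooling raw single-fold nulls instead is markedly conservative.
#' P-values use the add-one rule
#' `p = (1 + #(|null| >= |mean real|)) / (1 + n_perm)`; infinite sentinel
#' statistics (perfect fits) are excluded from the null comparisons with a
#' warning. Post hoc t p-values are BH-adjusted across the predictors of
#' the model.
#'
#' @param y Response vector.
#' @param x Predictor matrix (no intercept).
#' @param folds Fold assignment from [stratified_folds()].
#' @param n_perm Permutations per fold (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `fc_cv_result`: fold-wise `beta` matrix and
#'   statistics, `mean_F`, `mean_t`, null pools, `p_F`, `p_t`, `q_t`.
#' @export
cv_permutation_model <- function(y, x, folds, n_perm = 1000L, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  k <- attr(folds, "k")
  if (is.null(k)) k <- length(unique(folds))
  p <- ncol(x)
  x1 <- cbind(`(intercept)` = 1, x)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n <- length(y)
  fold_beta <- matrix(NA_real_, k, p + 1,
                      dimnames = list(NULL, colnames(x1)))
  fold_f <- numeric(k)
  fold_t <- matrix(NA_real_, k, p, dimnames = list(NULL, colnames(x)))
  null_f <- matrix(NA_real_, k, n_perm)
  null_t <- array(NA_real_, c(k, n_perm, p))

  # one permutation of y per null replicate, shared across folds so the null
  # fold-average has the same between-fold dependence as the real one
  yperm <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))

  for (fi in seq_len(k)) {
    test <- which(folds == fi - 1L)
    train <- which(folds != fi - 1L)
    pre <- .fold_precompute(y, x1, train, test)
    beta <- qr.coef(pre$qr_tr, pre$ytr)
    ev <- .eval_beta(beta, pre)
    fold_beta[fi, ] <- beta
    fold_f[fi] <- ev$F[1]
    fold_t[fi, ] <- ev$t[, 1]
    bp <- qr.coef(pre$qr_tr, yperm[train, , drop = FALSE])
    evp <- .eval_beta(bp, pre)
    null_f[fi, ] <- evp$F
    null_t[fi, , ] <- t(evp$t)
  }

  if (any(!is.finite(fold_f)))
    warning("infinite F sentinel in ", sum(!is.finite(fold_f)),
            " fold(s); excluded from averaging and null comparison")
  if (any(!is.finite(null_f)))
    warning("infinite null statistics excluded from the null comparisons")
  mean_f <- mean(fold_f[is.finite(fold_f)])
  mean_t <- colMeans(fold_t)
  null_f_avg <- colMeans(null_f)           # Inf propagates, then excluded
  null_t_avg <- apply(null_t, c(2, 3), mean)
  p_t <- vapply(seq_len(p), function(j) .perm_p(mean_t[j], null_t_avg[, j]),
                numeric(1))
  structure(list(fold_beta = fold_beta, fold_F = fold_f, fold_t = fold_t,
                 mean_F = mean_f, mean_t = mean_t,
                 null_F = as.vector(null_f),
                 null_t = matrix(null_t, k * n_perm, p,
                                 dimnames = list(NULL, colnames(x))),
                 null_F_avg = null_f_avg, null_t_avg = null_t_avg,
                 p_F = .perm_p(mean_f, null_f_avg),
                 p_t = stats::setNames(p_t, colnames(x)),
                 q_t = stats::setNames(fdr_adjust(p_t), colnames(x)),
                 k = k, n_perm = as.integer(n_perm), predictors = colnames(x)),
            class = "fc_cv_result")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone in the sorted order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hold-out validation of the cross-fold average model
#'
#' The fold coefficients are averaged into a single cross-fold model, which
#' is applied unchanged to a hold-out sample disjoint from the estimation
#' sample. F and t are computed exactly as in [fold_fit_eval()], treating the
#' hold-out set as the test fold; null distributions come from permuting the
#' hold-out response while keeping the averaged coefficients fixed. Add-one
#' p-values; BH adjustment across the post hoc t tests.
#'
#' @param result An `fc_cv_result`.
#' @param y_holdout,x_holdout Hold-out response and predictor matrix; the
#'   predictor columns must match the estimation model.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `fc_holdout_result` with `beta` (averaged),
#'   `F`, `t`, `p_F`, `p_t`, `q_t`, and the null pools.
#' @export
holdout_validation <- function(result, y_holdout, x_holdout,
                               n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(result, "fc_cv_result"))
  x_holdout <- as.matrix(x_holdout)
  if (!identical(colnames(x_holdout), result$predictors))
    stop("hold-out predictors do not match the estimation model")
  x1 <- cbind(`(intercept)` = 1, x_holdout)
  beta <- colMeans(result$fold_beta)
  n <- length(y_holdout)
  p <- ncol(x_holdout)
  if (n <= p + 1) stop("hold-out sample too small: need n > p + 1")
  xtx <- crossprod(x1)
  cinv_diag <- diag(chol2inv(chol(xtx)))
  pre <- list(xte = x1, yte = y_holdout, p = p, n_test = n,
              sstot = sum((y_holdout - mean(y_holdout))^2),
              cinv_diag = cinv_diag)
  ev <- .eval_beta(beta, pre)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  preds <- as.numeric(x1 %*% beta)
  yp <- vapply(seq_len(n_perm), function(b) y_holdout[sample.int(n)],
               numeric(n))
  ssr <- colSums((yp - preds)^2)
  dfe <- n - p - 1
  r2 <- 1 - ssr / pre$sstot
  null_f <- ifelse(ssr <= 1e-10 * max(pre$sstot, 1), Inf,
                   ifelse(r2 <= 0, 0, (r2 / p) / ((1 - r2) / dfe)))
  sigma2 <- ssr / dfe
  null_t <- t(beta[-1] / sqrt(outer(cinv_diag[-1], sigma2)))
  colnames(null_t) <- result$predictors

  p_t <- vapply(seq_len(p), function(j) .perm_p(ev$t[j, 1], null_t[, j]),
                numeric(1))
  structure(list(beta = beta, F = ev$F[1],
                 t = stats::setNames(ev$t[, 1], result$predictors),
                 r2 = ev$r2[1],
                 null_F = null_f, null_t = null_t,
                 p_F = .perm_p(ev$F[1], null_f),
                 p_t = stats::setNames(p_t, result$predictors),
                 q_t = stats::setNames(fdr_adjust(p_t), result$predictors),
                 n_perm = as.integer(n_perm)),
            class = "fc_holdout_result")
}

#' Spearman screen of one brain measure against task scores
#'
#' Spearman correlation of `x` with each task column, asymptotic p-values,
#' BH-adjusted q across the tasks. Constant columns are flagged and reported
#' as missing.
#'
#' @param x Numeric vector (e.g., a cluster's first-gradient coordinate).
#' @param tasks data.frame or matrix of task score columns (paired with `x`,
#'   n >= 5).
#' @return data.frame with `task`, `rho`, `p`, `q`, `flag`.
#' @export
spearman_screen <- function(x, tasks) {
  tasks <- as.data.frame(tasks)
  if (length(x) < 5) stop("need at least 5 paired observations")
  rows <- lapply(names(tasks), function(nm) {
    tv <- tasks[[nm]]
    if (stats::sd(tv) == 0 || stats::sd(x) == 0)
      return(data.frame(task = nm, rho = NA_real_, p = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, tv, method = "spearman",
                                           exact = FALSE))
    data.frame(task = nm, rho = unname(ct$estimate), p = ct$p.value,
               flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- fdr_adjust(out$p[ok])
  out[, c("task", "rho", "p", "q", "flag")]
}

#' @export
print.fc_cv_result <- function(x, ...) {
  cat(sprintf("fc_cv_result: %d folds, %d permutations/fold\n", x$k, x$n_perm))
  cat(sprintf("  mean out-of-sample F = %.4g (p = %.4g)\n", x$mean_F, x$p_F))
  tab <- data.frame(predictor = x$predictors, mean_t = x$mean_t,
                    p = x$p_t, q = x$q_t, row.names = NULL)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
print.fc_holdout_result <- function(x, ...) {
  cat(sprintf("fc_holdout_result: F = %.4g (p = %.4g), %d permutations\n",
              x$F, x$p_F, x$n_perm))
  tab <- data.frame(predictor = names(x$t), t = x$t, p = x$p_t, q = x$q_t,
                    row.names = NULL)
  print(tab, digits = 4)
  invisible(x)
}
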