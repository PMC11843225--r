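#' Multi-run vertex-by-time surface time series
#'
#' Container for one subject's BOLD-like time series sampled on a shared
#' mesh, with run boundaries retained so per-run normalization is possible.
#'
#' @param subject_id Character scalar.
#' @param data Vertex x time numeric matrix (finite).
#' @param run_lengths Integer vector of run lengths; must sum to `ncol(data)`
#'   with every run >= 2 timepoints.
#' @return An object of class `fc_timeseries`.
#' @export
surface_timeseries <- function(subject_id, data, run_lengths) {
  data <- as.matrix(data)
  run_lengths <- as.integer(run_lengths)
  if (!all(is.finite(data))) stop("time series must be finite")
  if (any(run_lengths < 2)) stop("every run must have >= 2 timepoints")
  if (sum(run_lengths) != ncol(data))
    stop("run lengths must partition the time axis")
  structure(list(subject_id = as.character(subject_id), data = data,
                 run_lengths = run_lengths),
            class = "fc_timeseries")
}

run_index <- function(ts) rep(seq_along(ts$run_lengths), ts$run_lengths)

#' Normalize runs and concatenate
#'
#' Z-scores each vertex's series within each run (mean 0, unit variance, sd
#' with n-1 denominator) and concatenates the runs in order. Constant series
#' map to all-zeros rather than dropping the vertex, keeping vertex indexing
#' stable across subjects.
#'
#' @param ts An `fc_timeseries`.
#' @return An `fc_timeseries` with the same run structure.
#' @export
normalize_concatenate <- function(ts) {
  stopifnot(inherits(ts, "fc_timeseries"))
  out <- ts$data
  pos <- 0L
  for (tr in ts$run_lengths) {
    idx <- pos + seq_len(tr)
    blk <- ts$data[, idx, drop = FALSE]
    m <- rowMeans(blk)
    blk <- blk - m
    s <- sqrt(rowSums(blk^2) / (tr - 1))
    s[s == 0] <- Inf   # constant series -> zeros
    out[, idx] <- blk / s
    pos <- pos + tr
  }
  surface_timeseries(ts$subject_id, out, ts$run_lengths)
}

#' Per-subject component decomposition
#'
#' First step of the two-stage group embedding: the top-r singular triplets
#' of the (normalized, concatenated) vertex x time matrix. `scores` holds the
#' r left singular vectors (unit-norm, mutually orthogonal spatial
#' components); `variance_fractions` are sigma_i^2 over the total sum of all
#' squared singular values.
#'
#' @param ts An `fc_timeseries` (normalize first with
#'   [normalize_concatenate()]).
#' @param r Number of components to keep; when `NULL`, the smallest r whose
#'   cumulative variance fraction reaches `target_variance`, capped at
#'   `max_rank`.
#' @param target_variance Cumulative variance target for automatic r
#'   (default 0.5).
#' @param max_rank Cap on automatic r (default 10).
#' @return An object of class `fc_components` with `subject_id`, `scores`
#'   (vertex x r), `singular_values`, `variance_fractions`, and
#'   `total_variance`.
#' @export
subject_decomposition <- function(ts, r = NULL, target_variance = 0.5,
                                  max_rank = 10L) {
  stopifnot(inherits(ts, "fc_timeseries"))
  x <- ts$data
  rank_bound <- min(dim(x))
  sv <- svd(x, nu = 0, nv = 0)$d
  tot <- sum(sv^2)
  if (tot == 0) stop("all-zero time series cannot be decomposed")
  if (is.null(r)) {
    cum <- cumsum(sv^2) / tot
    r <- min(which(cum >= target_variance), max_rank)
  }
  if (r < 1 || r > rank_bound)
    stop("r must lie in [1, min(vertices, timepoints)]")
  dec <- svd(x, nu = r, nv = 0)
  structure(list(subject_id = ts$subject_id,
                 scores = dec$u,
                 singular_values = dec$d[seq_len(r)],
                 variance_fractions = dec$d[seq_len(r)]^2 / tot,
                 total_variance = tot),
            class = "fc_components")
}

#' Group-level embedding of concatenated subject components
#'
#' Second step of the two-stage group embedding: singular value decomposition
#' of the column-wise concatenation of all subjects' component score
#' matrices (each subject's columns scaled to unit norm first, so every
#' subject contributes equal energy). The top-k left singular vectors are the
#' group gradients, ordered by group singular value.
#'
#' @param components List of `fc_components`, all on the same vertex set.
#' @param k Number of gradients to retain (default 3).
#' @param template Optional vertex x k matrix; each gradient's sign is fixed
#'   so its correlation with the matching template column is positive.
#'   Without a template, the largest-magnitude element is made positive.
#' @return An object of class `fc_group_embedding` with `gradients`
#'   (vertex x k, mutually orthogonal unit-norm columns),
#'   `group_singular_values` (all values, nonincreasing), and `k`.
#' @export
group_decomposition <- function(components, k = 3L, template = NULL) {
  stopifnot(length(components) >= 1)
  nv <- vapply(components, function(cm) nrow(cm$scores), integer(1))
  if (length(unique(nv)) != 1) stop("subjects must share the vertex count")
  total_cols <- sum(vapply(components, function(cm) ncol(cm$scores), integer(1)))
  if (k > total_cols) stop("k exceeds the number of concatenated components")
  mats <- lapply(components, function(cm) {
    sc <- cm$scores
    nrm <- sqrt(colSums(sc^2))
    if (any(nrm == 0)) stop("subject scores contain a zero column")
    sweep(sc, 2, nrm, `/`)
  })
  m <- do.call(cbind, mats)
  dec <- svd(m, nu = k, nv = 0)
  g <- dec$u
  for (j in seq_len(k)) {
    flip <- if (!is.null(template)) {
      stats::cor(g[, j], template[, j]) < 0
    } else g[which.max(abs(g[, j])), j] < 0
    if (isTRUE(flip)) g[, j] <- -g[, j]
  }
  structure(list(gradients = g, group_singular_values = dec$d, k = as.integer(k)),
            class = "fc_group_embedding")
}

#' Project a subject into the group gradient space
#'
#' Least-squares representation of each group gradient within the subject's
#' component subspace: `coords[, j] = scores %*% (scores^+ %*% gradient_j)`,
#' where the pseudoinverse reduces to the transpose because the score columns
#' are orthonormal. Signs are then aligned to the group gradients via
#' [align_signs()].
#'
#' @param comp An `fc_components`.
#' @param group An `fc_group_embedding` on the same vertex set.
#' @return An object of class `fc_subject_embedding` with `coords`
#'   (vertex x k), `sign_flips` and `zero_variance` flags.
#' @export
project_subject <- function(comp, group) {
  stopifnot(inherits(comp, "fc_components"), inherits(group, "fc_group_embedding"))
  if (nrow(comp$scores) != nrow(group$gradients))
    stop("vertex counts differ between subject and group")
  if (any(comp$singular_values <= 1e-12 * comp$singular_values[1]))
    stop("rank-deficient subject scores")
  u <- sweep(comp$scores, 2, sqrt(colSums(comp$scores^2)), `/`)
  coords <- u %*% (t(u) %*% group$gradients)
  emb <- structure(list(subject_id = comp$subject_id, coords = coords,
                        sign_flips = rep(1L, group$k),
                        zero_variance = rep(FALSE, group$k)),
                   class = "fc_subject_embedding")
  align_signs(emb, group)
}

#' Align the signs of a subject embedding to the group gradients
#'
#' SVD leaves each axis's sign arbitrary; each coordinate column whose
#' Pearson correlation with the matching group gradient is negative is
#' multiplied by -1. Zero-variance columns are flagged and left at +1.
#'
#' @param emb An `fc_subject_embedding`.
#' @param group An `fc_group_embedding` with matching shape.
#' @return The embedding with aligned `coords`, recorded `sign_flips`, and
#'   `zero_variance` flags.
#' @export
align_signs <- function(emb, group) {
  stopifnot(inherits(emb, "fc_subject_embedding"),
            inherits(group, "fc_group_embedding"))
  if (!all(dim(emb$coords) == dim(group$gradients)))
    stop("embedding and group gradient shapes differ")
  flips <- rep(1L, ncol(emb$coords))
  zv <- rep(FALSE, ncol(emb$coords))
  for (j in seq_len(ncol(emb$coords))) {
    if (stats::sd(emb$coords[, j]) == 0) {
      zv[j] <- TRUE
      next
    }
    if (stats::cor(emb$coords[, j], group$gradients[, j]) < 0) {
      emb$coords[, j] <- -emb$coords[, j]
      flips[j] <- -1L
    }
  }
  emb$sign_flips <- flips
  emb$zero_variance <- zv
  if (any(zv)) warning("zero-variance embedding column(s): ",
                       paste(which(zv), collapse = ", "))
  emb
}

#' Variance-explained profile of the two-step embedding
#'
#' The two-step construction has no single explained-variance number, so two
#' metrics are reported per component index i: `individual_fraction`, the
#' mean over subjects of the subject-level variance fraction of component i;
#' and `weighted_fraction`, that mean multiplied by the cumulative group-level
#' explained-variance fraction up to i.
#'
#' @param components List of `fc_components`.
#' @param group An `fc_group_embedding` built from them.
#' @return An object of class `fc_variance_profile`: list with
#'   `individual_fraction` and `weighted_fraction`, both in \[0, 1\] with
#'   `weighted_fraction <= individual_fraction` elementwise.
#' @export
variance_profile <- function(components, group) {
  stopifnot(length(components) >= 1, inherits(group, "fc_group_embedding"))
  r_min <- min(vapply(components, function(cm) length(cm$variance_fractions),
                      integer(1)))
  vf <- vapply(components,
               function(cm) cm$variance_fractions[seq_len(r_min)],
               numeric(r_min))
  vf <- matrix(vf, nrow = r_min)
  indiv <- rowMeans(vf)
  gsv2 <- group$group_singular_values^2
  cumfrac <- cumsum(gsv2) / sum(gsv2)
  n_out <- min(r_min, length(cumfrac))
  structure(list(individual_fraction = indiv[seq_len(n_out)],
                 weighted_fraction = indiv[seq_len(n_out)] * cumfrac[seq_len(n_out)]),
            class = "fc_variance_profile")
}

#' Embed a cohort end to end
#'
#' Convenience wrapper: normalizes each subject's runs, computes per-subject
#' components (automatic rank unless `r` given), the group embedding, and
#' sign-aligned subject projections.
#'
#' @param timeseries List of `fc_timeseries`.
#' @param k Gradients to retain (default 3).
#' @param r Per-subject component count, or `NULL` for automatic selection.
#' @param template Optional sign template passed to [group_decomposition()].
#' @inheritParams subject_decomposition
#' @return List with `components`, `group`, `embeddings`, `profile`.
#' @export
embed_cohort <- function(timeseries, k = 3L, r = NULL, target_variance = 0.5,
                         max_rank = 10L, template = NULL) {
  comps <- lapply(timeseries, function(ts)
    subject_decomposition(normalize_concatenate(ts), r = r,
                          target_variance = target_variance,
                          max_rank = max_rank))
  group <- group_decomposition(comps, k = k, template = template)
  embs <- lapply(comps, project_subject, group = group)
  names(embs) <- names(comps)
  list(components = comps, group = group, embeddings = embs,
       profile = variance_profile(comps, group))
}
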