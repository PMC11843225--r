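#' Cross-subject dispersion of vertices in gradient space
#'
#' For every vertex, the group-level centroid is the arithmetic mean of the
#' subjects' K-dimensional gradient coordinates; dispersion is the sum of
#' squared Euclidean distances of the individual subjects from it, decomposed
#' additively per axis. The mean (not the median) is used because it is the
#' minimizer of the sum-of-squared-distances statistic.
#'
#' @param embeddings List of >= 2 `fc_subject_embedding`s with identical
#'   coordinate shapes.
#' @param normalize If `TRUE`, divide dispersions by (n - 1) for
#'   cross-cohort comparability (default `FALSE`: raw sums of squares).
#' @return An object of class `fc_dispersion`: list with `total` (per-vertex
#'   scalar), `per_axis` (vertex x K), `centroids` (vertex x K),
#'   `n_subjects`, `normalized`. `total` equals `rowSums(per_axis)` exactly
#'   up to float tolerance.
#' @export
vertex_dispersion <- function(embeddings, normalize = FALSE) {
  if (length(embeddings) < 2) stop("need >= 2 subjects to measure dispersion")
  dims <- unique(lapply(embeddings, function(e) dim(e$coords)))
  if (length(dims) != 1) stop("embeddings must share coordinate shape")
  n <- length(embeddings)
  centroid <- Reduce(`+`, lapply(embeddings, `[[`, "coords")) / n
  per_axis <- 0
  for (e in embeddings) per_axis <- per_axis + (e$coords - centroid)^2
  if (normalize) per_axis <- per_axis / (n - 1)
  structure(list(total = rowSums(per_axis), per_axis = per_axis,
                 centroids = centroid, n_subjects = n,
                 normalized = normalize),
            class = "fc_dispersion")
}

#' Correlate total dispersion with per-axis dispersion and gradient position
#'
#' Spearman correlations across vertices between the total dispersion map
#' and (a) the dispersion measured along each gradient axis separately and
#' (b) each group gradient's vertex values, with BH/FDR-adjusted p-values
#' across all tests in the table. Constant inputs yield an undefined rho,
#' reported as `NA` with `flag = "constant"`.
#'
#' @param map An `fc_dispersion`.
#' @param group An `fc_group_embedding` with matching vertex count.
#' @return data.frame with columns `variable`, `rho`, `p`, `q`, `flag`.
#' @export
axis_dispersion_correlation <- function(map, group) {
  stopifnot(inherits(map, "fc_dispersion"), inherits(group, "fc_group_embedding"))
  if (nrow(group$gradients) != length(map$total))
    stop("vertex counts differ")
  k <- ncol(map$per_axis)
  vars <- cbind(map$per_axis, group$gradients)
  labels <- c(paste0("axis_dispersion_", seq_len(k)),
              paste0("gradient_", seq_len(group$k)))
  rows <- lapply(seq_len(ncol(vars)), function(j) {
    x <- vars[, j]
    if (stats::sd(x) == 0 || stats::sd(map$total) == 0)
      return(data.frame(variable = labels[j], rho = NA_real_, p = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(map$total, x, method = "spearman",
                                           exact = FALSE))
    data.frame(variable = labels[j], rho = unname(ct$estimate), p = ct$p.value,
               flag = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- fdr_adjust(out$p[ok])
  out[, c("variable", "rho", "p", "q", "flag")]
}

#' Extract maximal-variability clusters from a dispersion map
#'
#' Thresholds the total dispersion map at a percentile (linear-interpolation
#' quantile; strictly-greater comparison), partitions the suprathreshold
#' vertices into connected components under mesh edge adjacency, discards
#' components whose summed vertex area falls below `min_area_mm2`, and
#' orders the surviving clusters by descending area.
#'
#' @param map An `fc_dispersion`.
#' @param mesh The `fc_mesh` the map lives on.
#' @param percentile Threshold percentile in (0, 100) (default 95).
#' @param min_area_mm2 Minimum cluster area (default 200 mm^2).
#' @return An object of class `fc_clusters`: `labels` (per-vertex integer,
#'   0 = background), `clusters` (data.frame: id, n_vertices, area_mm2),
#'   `vertices` (list of vertex index vectors), `threshold_value`,
#'   `percentile`, `min_area_mm2`. No suprathreshold vertices gives an empty
#'   cluster set, not an error.
#' @export
extract_clusters <- function(map, mesh, percentile = 95, min_area_mm2 = 200) {
  stopifnot(inherits(map, "fc_dispersion"), inherits(mesh, "fc_mesh"))
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  if (min_area_mm2 < 0) stop("min_area_mm2 must be >= 0")
  if (length(map$total) != mesh$n_vertices)
    stop("dispersion map and mesh vertex counts differ")
  thr <- unname(stats::quantile(map$total, percentile / 100, type = 7))
  supra <- which(map$total > thr)
  labels <- integer(mesh$n_vertices)
  if (length(supra) == 0)
    return(structure(list(labels = labels,
                          clusters = data.frame(id = integer(0),
                                                n_vertices = integer(0),
                                                area_mm2 = numeric(0)),
                          vertices = list(), threshold_value = thr,
                          percentile = percentile,
                          min_area_mm2 = min_area_mm2),
                     class = "fc_clusters"))
  keep <- mesh$edges[, 1] %in% supra & mesh$edges[, 2] %in% supra
  relabel <- integer(mesh$n_vertices)
  relabel[supra] <- seq_along(supra)
  g <- igraph::graph_from_edgelist(
    cbind(relabel[mesh$edges[keep, 1]], relabel[mesh$edges[keep, 2]]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(supra) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  verts <- split(supra, comp)
  areas <- vapply(verts, function(v) sum(mesh$vertex_area[v]), numeric(1))
  keep_c <- areas >= min_area_mm2 & min_area_mm2 >= 0
  verts <- verts[keep_c]; areas <- areas[keep_c]
  ord <- order(-areas, vapply(verts, min, integer(1)))
  verts <- verts[ord]; areas <- areas[ord]
  clusters <- data.frame(id = seq_along(verts),
                         n_vertices = lengths(verts),
                         area_mm2 = as.numeric(areas))
  for (i in seq_along(verts)) labels[verts[[i]]] <- i
  names(verts) <- NULL
  structure(list(labels = labels, clusters = clusters,
                 vertices = lapply(verts, sort), threshold_value = thr,
                 percentile = percentile, min_area_mm2 = min_area_mm2),
            class = "fc_clusters")
}

#' Per-subject cluster-mean gradient coordinates
#'
#' For every subject, cluster and gradient axis, the mean of the subject's
#' aligned coordinates over the cluster's vertices: the predictors of the
#' brain-behavior models.
#'
#' @param embeddings List of `fc_subject_embedding`s.
#' @param clusters A nonempty `fc_clusters`.
#' @return Numeric matrix, one row per subject, columns named
#'   `c<cluster>_g<axis>`.
#' @export
cluster_coordinates <- function(embeddings, clusters) {
  stopifnot(inherits(clusters, "fc_clusters"))
  if (nrow(clusters$clusters) == 0) stop("cluster set is empty")
  k <- ncol(embeddings[[1]]$coords)
  n_cl <- nrow(clusters$clusters)
  # values laid out cluster-fastest within each axis, matching cn
  cn <- as.vector(outer(seq_len(n_cl), seq_len(k),
                        function(ci, gi) sprintf("c%d_g%d", ci, gi)))
  out <- t(vapply(embeddings, function(e) {
    as.vector(vapply(seq_len(k), function(gi)
      vapply(clusters$vertices, function(v) mean(e$coords[v, gi]), numeric(1)),
      numeric(n_cl)))
  }, numeric(length(cn))))
  dimnames(out) <- list(vapply(embeddings, `[[`, character(1), "subject_id"), cn)
  out[, order(colnames(out)), drop = FALSE]
}

#' @export
print.fc_clusters <- function(x, ...) {
  cat(sprintf("fc_clusters: %d cluster(s) above the %.4g threshold (%.0fth pct, min area %.0f mm^2)\n",
              nrow(x$clusters), x$threshold_value, x$percentile, x$min_area_mm2))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
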