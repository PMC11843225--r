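#' Augment an atlas parcellation with variability clusters
#'
#' Cluster vertices are removed from their original atlas parcels ("masking"
#' the overlap) and the clusters are appended as new parcels assigned to a
#' dedicated `"cluster"` community; original parcels left empty are dropped.
#' The percentage of each cluster's vertices overlapping every original
#' community is reported.
#'
#' @param atlas_labels Per-vertex parcel label (integer or character; `NA`
#'   or `0` = unassigned).
#' @param clusters An `fc_clusters` on the same vertex space.
#' @param communities Named vector mapping every atlas parcel label to one of
#'   the canonical network communities.
#' @return An object of class `fc_parcellation`: `labels` (per-vertex
#'   character, `NA` = unassigned), `parcels` (data.frame: parcel,
#'   community, n_vertices), `vertices` (named list), and `overlap`
#'   (data.frame of cluster x community overlap percentages summing to 100
#'   per cluster).
#' @export
augment_parcellation <- function(atlas_labels, clusters, communities) {
  stopifnot(inherits(clusters, "fc_clusters"))
  labels <- as.character(atlas_labels)
  labels[labels %in% "0"] <- NA_character_
  if (length(labels) != length(clusters$labels))
    stop("atlas and clusters must share the vertex space")
  if (!all(stats::na.omit(unique(labels)) %in% names(communities)))
    stop("every atlas parcel needs a community assignment")

  overlap <- NULL
  for (i in seq_len(nrow(clusters$clusters))) {
    cv <- clusters$vertices[[i]]
    orig <- labels[cv]
    if (all(is.na(orig)))
      stop("cluster ", i, " covers no atlas vertex")
    comm <- ifelse(is.na(orig), "unassigned", unname(communities[orig]))
    pct <- 100 * table(comm) / length(cv)
    overlap <- rbind(overlap,
                     data.frame(cluster = i, community = names(pct),
                                percent = as.numeric(pct),
                                stringsAsFactors = FALSE))
    labels[cv] <- sprintf("cluster_%d", i)
  }

  keep <- !is.na(labels)
  verts <- split(which(keep), labels[keep])
  parcel_names <- names(verts)
  comm_of <- ifelse(grepl("^cluster_", parcel_names), "cluster",
                    unname(communities[parcel_names]))
  parcels <- data.frame(parcel = parcel_names, community = comm_of,
                        n_vertices = lengths(verts),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(labels = labels, parcels = parcels, vertices = verts,
                 overlap = overlap),
            class = "fc_parcellation")
}

#' Parcel-averaged time series
#'
#' Each parcel's series is the unweighted mean of its vertices' series.
#'
#' @param ts An `fc_timeseries`.
#' @param parc An `fc_parcellation` on the same vertex space.
#' @return Numeric node x time matrix, rows named and ordered as
#'   `parc$parcels$parcel`.
#' @export
parcel_timeseries <- function(ts, parc) {
  stopifnot(inherits(ts, "fc_timeseries"), inherits(parc, "fc_parcellation"))
  if (nrow(ts$data) != length(parc$labels))
    stop("vertex counts differ between time series and parcellation")
  out <- t(vapply(parc$parcels$parcel, function(pn)
    colMeans(ts$data[parc$vertices[[pn]], , drop = FALSE]),
    numeric(ncol(ts$data))))
  rownames(out) <- parc$parcels$parcel
  out
}

#' Density-thresholded positive correlation graph
#'
#' Pearson correlations between node time series; self-connections removed;
#' the `floor(density * n * (n-1) / 2)` largest strictly positive edges are
#' retained (ties broken by lexicographic node-pair order). Negative and
#' zero correlations are never retained; if fewer positive edges exist than
#' the density asks for, all positive edges are kept with a warning.
#' Constant node series have undefined correlations, treated as 0 with a
#' warning.
#'
#' @param node_ts Node x time matrix (>= 3 timepoints).
#' @param density Fraction of all possible edges to retain, in (0, 1\]
#'   (default 0.10).
#' @param communities Optional per-node community labels (character or
#'   factor), carried on the graph for the participation coefficient.
#' @return An object of class `fc_graph`: `weights` (symmetric matrix, zero
#'   diagonal, entries in (0, 1\]), `density`, `n_edges`, `communities`,
#'   `nodes`.
#' @export
correlation_graph <- function(node_ts, density = 0.10, communities = NULL) {
  node_ts <- as.matrix(node_ts)
  n <- nrow(node_ts)
  if (ncol(node_ts) < 3) stop("need at least 3 timepoints")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  sds <- apply(node_ts, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(node_ts)))
  if (any(sds == 0)) {
    warning("constant node series; undefined correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 0
  idx <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[idx]
  pos <- w > 0
  idx <- idx[pos, , drop = FALSE]
  w <- w[pos]
  m_target <- floor(density * n * (n - 1) / 2)
  if (length(w) < m_target)
    warning("only ", length(w), " positive edges available for a target of ",
            m_target, "; keeping all")
  m <- min(m_target, length(w))
  ord <- order(-w, idx[, 1], idx[, 2])[seq_len(m)]
  wm <- matrix(0, n, n)
  wm[idx[ord, , drop = FALSE]] <- w[ord]
  wm <- wm + t(wm)
  nodes <- rownames(node_ts)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  dimnames(wm) <- list(nodes, nodes)
  if (!is.null(communities)) {
    communities <- as.character(communities)
    stopifnot(length(communities) == n)
  }
  structure(list(weights = wm, density = density, n_edges = m,
                 communities = communities, nodes = nodes),
            class = "fc_graph")
}

#' Six weighted node metrics
#'
#' Computed on the thresholded weighted graph with path lengths `1/weight`:
#' strength (sum of edge weights); global efficiency (mean inverse shortest
#' path length to all other nodes, 0 for unreachable pairs); local
#' efficiency (global efficiency of the subgraph induced by the node's
#' neighbors); clustering coefficient (geometric-mean triangle form on
#' weights normalized by the maximum retained weight); betweenness
#' centrality (shortest-path counts through the node, fractions summed over
#' ties); and participation coefficient `1 - sum_m (k_im / k_i)^2` over the
#' community structure with weighted degrees. Isolated nodes score 0 on
#' efficiency, clustering and participation by convention.
#'
#' @param g An `fc_graph` (communities required for participation).
#' @return data.frame, one row per node: `strength`, `global_efficiency`,
#'   `local_efficiency`, `clustering`, `betweenness`, `participation`.
#' @export
node_metrics <- function(g) {
  stopifnot(inherits(g, "fc_graph"))
  w <- g$weights
  n <- nrow(w)
  if (n == 0) stop("empty graph")
  strength <- rowSums(w)

  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  ew <- igraph::E(ig)$weight
  d <- if (length(ew)) igraph::distances(ig, weights = 1 / ew) else
    matrix(Inf, n, n)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  geff <- if (n > 1) rowSums(inv) / (n - 1) else 0

  leff <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    .graph_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))

  wmax <- max(w)
  cl <- numeric(n)
  if (wmax > 0) {
    wn <- (w / wmax)^(1 / 3)
    cyc <- diag(wn %*% wn %*% wn)
    deg <- rowSums(w > 0)
    cl <- ifelse(deg >= 2, cyc / (deg * (deg - 1)), 0)
  }

  btw <- if (length(ew)) igraph::betweenness(ig, weights = 1 / ew) else
    numeric(n)

  part <- rep(0, n)
  if (!is.null(g$communities)) {
    comm <- factor(g$communities)
    kim <- t(rowsum(t(w), comm))   # node x community weighted degree
    part <- ifelse(strength > 0, 1 - rowSums((kim / strength)^2), 0)
  }

  data.frame(node = g$nodes, strength = strength,
             global_efficiency = as.numeric(geff),
             local_efficiency = leff, clustering = as.numeric(cl),
             betweenness = as.numeric(btw), participation = as.numeric(part),
             stringsAsFactors = FALSE, row.names = NULL)
}

# mean inverse shortest-path length over ordered node pairs of a weighted
# adjacency matrix (lengths 1/w); the "global efficiency of a subgraph"
.graph_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  ew <- igraph::E(ig)$weight
  d <- if (length(ew)) igraph::distances(ig, weights = 1 / ew) else
    igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Z-profile of target nodes across subjects
#'
#' Within each subject, every metric is z-scored across all nodes (sample
#' standard deviation); the target nodes' z-values are then averaged across
#' subjects. A metric with zero variance across nodes in some subject is
#' flagged and skipped for that subject.
#'
#' @param metrics_list List (one element per subject) of [node_metrics()]
#'   data.frames over the same node set.
#' @param target_nodes Character vector of node names to profile.
#' @return data.frame of mean z-values, rows = target nodes, columns = the
#'   six metrics, with attribute `flagged` naming any subject/metric pairs
#'   with undefined z.
#' @export
metric_zprofile <- function(metrics_list, target_nodes) {
  stopifnot(length(metrics_list) >= 1)
  mets <- setdiff(names(metrics_list[[1]]), "node")
  flagged <- character(0)
  acc <- array(NA_real_, c(length(metrics_list), length(target_nodes),
                           length(mets)))
  for (s in seq_along(metrics_list)) {
    df <- metrics_list[[s]]
    if (nrow(df) < 2) stop("need >= 2 nodes per subject")
    ti <- match(target_nodes, df$node)
    if (anyNA(ti)) stop("target node(s) missing from subject ", s)
    for (mi in seq_along(mets)) {
      x <- df[[mets[mi]]]
      sdx <- stats::sd(x)
      if (sdx == 0) {
        flagged <- c(flagged, sprintf("subject %d: %s", s, mets[mi]))
        next
      }
      acc[s, , mi] <- ((x - mean(x)) / sdx)[ti]
    }
  }
  out <- apply(acc, c(2, 3), function(v) mean(v, na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out <- as.data.frame(out)
  dimnames(out) <- list(target_nodes, mets)
  attr(out, "flagged") <- flagged
  out
}

#' Association between a cluster's gradient position and its topology
#'
#' Spearman correlation, across subjects, between a cluster's gradient
#' coordinate and each of its topological metrics, with BH adjustment across
#' the metrics. Constant metrics are flagged and reported missing.
#'
#' @param cluster_axis Per-subject gradient coordinate of the cluster.
#' @param metrics Per-subject metric values for that cluster: data.frame or
#'   matrix with one row per subject and one column per metric.
#' @return data.frame with `metric`, `rho`, `p`, `q`, `flag`.
#' @export
gradient_topology_association <- function(cluster_axis, metrics) {
  metrics <- as.data.frame(metrics)
  if (length(cluster_axis) != nrow(metrics))
    stop("cluster_axis and metrics must be paired across subjects")
  if (length(cluster_axis) < 5) stop("need at least 5 subjects")
  out <- spearman_screen(cluster_axis, metrics)
  names(out)[names(out) == "task"] <- "metric"
  out
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("fc_graph: %d nodes, %d edges (density %.2f)%s\n",
              length(x$nodes), x$n_edges, x$density,
              if (is.null(x$communities)) "" else
                sprintf(", %d communities", length(unique(x$communities)))))
  invisible(x)
}
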