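# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code path with the package: distances via
# Floyd-Warshall, betweenness via unique-shortest-path membership (valid for
# continuous weights), components via flood fill, FDR via the literal
# step-up definition, Spearman via the rank-difference formula.

make_emb <- function(coords, id = "s") {
  structure(list(subject_id = id, coords = coords,
                 sign_flips = rep(1L, ncol(coords)),
                 zero_variance = rep(FALSE, ncol(coords))),
            class = "fc_subject_embedding")
}

random_weighted_graph <- function(n, p_edge = 0.3, communities = TRUE) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < p_edge]
  w[on] <- runif(length(on), 0.05, 1)
  w <- w + t(w)
  nodes <- paste0("n", seq_len(n))
  dimnames(w) <- list(nodes, nodes)
  comm <- if (communities) sample(paste0("m", 1:4), n, replace = TRUE) else NULL
  structure(list(weights = w, density = 1, n_edges = length(on),
                 communities = comm, nodes = nodes),
            class = "fc_graph")
}

oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

oracle_global_efficiency <- function(w, d = oracle_distances(w)) {
  n <- nrow(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    dd <- oracle_distances(sub)
    inv <- 1 / dd
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wm <- max(w)
  if (wm == 0) return(numeric(n))
  wn <- w / wm
  vapply(seq_len(n), function(i) {
    deg <- sum(w[i, ] > 0)
    if (deg < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    acc / (deg * (deg - 1))
  }, numeric(1))
}

# assumes unique shortest paths (continuous random weights): node i lies on
# the u-v geodesic iff d(u,i) + d(i,v) = d(u,v)
oracle_betweenness <- function(w, d = oracle_distances(w), tol = 1e-9) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    on <- abs(outer(d[, i], d[i, ], `+`) - d) < tol & is.finite(d)
    on[i, ] <- FALSE
    on[, i] <- FALSE
    diag(on) <- FALSE
    sum(on) / 2
  }, numeric(1))
}

oracle_participation <- function(w, communities) {
  n <- nrow(w)
  comm <- unique(communities)
  vapply(seq_len(n), function(i) {
    k_i <- sum(w[i, ])
    if (k_i == 0) return(0)
    1 - sum(vapply(comm, function(m)
      (sum(w[i, communities == m]) / k_i)^2, numeric(1)))
  }, numeric(1))
}

oracle_flood_fill <- function(supra, neighbors) {
  remaining <- supra
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!(v %in% remaining)) next
      remaining <- setdiff(remaining, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(neighbors[[v]], remaining))
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(1, p[ord[i]] * n / i, prev)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# rank-difference formula; valid when there are no ties
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
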