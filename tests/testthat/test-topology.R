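toy_clusters <- function(v, vertex_sets) {
  labels <- integer(v)
  for (i in seq_along(vertex_sets)) labels[vertex_sets[[i]]] <- i
  structure(list(labels = labels,
                 clusters = data.frame(id = seq_along(vertex_sets),
                                       n_vertices = lengths(vertex_sets),
                                       area_mm2 = as.numeric(lengths(vertex_sets))),
                 vertices = vertex_sets, threshold_value = 0,
                 percentile = 95, min_area_mm2 = 0),
            class = "fc_clusters")
}

test_that("parcellation augmentation masks overlap and conserves cluster vertices", {
  # 4-parcel toy atlas on 20 vertices
  atlas <- rep(c("A", "B", "C", "D"), each = 5)
  comm <- c(A = "visual", B = "default", C = "visual", D = "frontoparietal")

  # cluster strictly inside parcel B: 5 parcels, donor shrunk
  cl <- toy_clusters(20, list(7:9))
  parc <- augment_parcellation(atlas, cl, comm)
  expect_equal(nrow(parc$parcels), 5L)
  expect_equal(parc$parcels$n_vertices[parc$parcels$parcel == "B"], 2L)
  expect_equal(parc$parcels$community[parc$parcels$parcel == "cluster_1"],
               "cluster")
  expect_equal(sum(parc$overlap$percent[parc$overlap$cluster == 1]), 100)
  expect_equal(parc$overlap$community, "default")

  # cluster exactly covering parcel C: total parcel count unchanged (+1 -1)
  cl2 <- toy_clusters(20, list(11:15))
  parc2 <- augment_parcellation(atlas, cl2, comm)
  expect_equal(nrow(parc2$parcels), 4L)
  expect_false("C" %in% parc2$parcels$parcel)

  # cluster with no atlas coverage is an error
  atlas_na <- atlas
  atlas_na[7:9] <- NA
  expect_error(augment_parcellation(atlas_na, cl, comm), "no atlas vertex")
  # overlap spanning two parcels sums to 100
  cl3 <- toy_clusters(20, list(4:7))
  parc3 <- augment_parcellation(atlas, cl3, comm)
  expect_equal(sum(parc3$overlap$percent), 100)
})

test_that("parcel time series are unweighted vertex means", {
  set.seed(6)
  dat <- matrix(rnorm(8 * 10), 8, 10)
  dat[3, ] <- dat[2, ]  # two identical vertices
  ts <- surface_timeseries("a", dat, 10)
  atlas <- c("P1", "P2", "P2", "P3", "P3", "P3", "P3", "P3")
  comm <- c(P1 = "visual", P2 = "default", P3 = "limbic")
  parc <- augment_parcellation(atlas, toy_clusters(8, list(8L)), comm)
  nts <- parcel_timeseries(ts, parc)
  expect_equal(nts["P1", ], dat[1, ])                  # single-vertex parcel
  expect_equal(nts["P2", ], dat[2, ])                  # identical vertices
  expect_equal(nts["P3", ], colMeans(dat[4:7, ]))      # direct mean oracle
  expect_equal(nts["cluster_1", ], dat[8, ])
})

test_that("correlation graphs keep exactly the strongest positive edges", {
  # hand case: series [1,2,3],[1,2,3],[3,2,1]
  nts <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  expect_warning(g <- correlation_graph(nts, density = 1), "positive edges")
  expect_equal(g$n_edges, 1L)
  expect_equal(g$weights[1, 2], 1)
  expect_true(all(g$weights[3, ] == 0))

  # 5 nodes, 10 possible edges, density 0.10 -> single largest edge
  set.seed(8)
  nts5 <- matrix(rnorm(5 * 30), 5, 30)
  g5 <- correlation_graph(nts5, density = 0.10)
  r <- cor(t(nts5)); diag(r) <- 0
  expect_equal(g5$n_edges, 1L)
  expect_equal(max(g5$weights), max(r))

  # random 20-node case vs the sort-and-cut oracle
  nts20 <- matrix(rnorm(20 * 40), 20, 40)
  g20 <- correlation_graph(nts20, density = 0.10)
  m <- floor(0.10 * 20 * 19 / 2)
  expect_equal(g20$n_edges, m)
  r20 <- cor(t(nts20)); diag(r20) <- 0
  up <- r20[upper.tri(r20)]
  cutoff <- sort(up[up > 0], decreasing = TRUE)[m]
  got <- g20$weights[upper.tri(g20$weights)]
  expect_setequal(got[got > 0], up[up >= cutoff])
  expect_true(all(got >= 0))
  expect_equal(sum(g20$weights > 0), 2L * m)  # symmetric
  expect_true(all(diag(g20$weights) == 0))

  # constant node: undefined correlations become 0 with a warning
  ntsc <- rbind(nts5, rep(1, 30))
  expect_warning(gc <- correlation_graph(ntsc, density = 0.2), "constant")
  expect_true(all(gc$weights[6, ] == 0))
})

test_that("too few positive correlations triggers the keep-all warning", {
  nts <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 2, 3, 4) * -1 + 5)
  expect_warning(g <- correlation_graph(nts, density = 1), "positive edges")
  expect_lte(g$n_edges, 1L)
})

test_that("node metrics reproduce the textbook hand cases", {
  tri <- structure(list(weights = matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                                         dimnames = list(letters[1:3], letters[1:3])),
                        density = 1, n_edges = 3, communities = NULL,
                        nodes = letters[1:3]),
                   class = "fc_graph")
  mt <- node_metrics(tri)
  expect_equal(mt$clustering, rep(1, 3))
  expect_equal(mt$strength, rep(2, 3))
  expect_equal(mt$global_efficiency, rep(1, 3))

  # path graph 1-2-3: node efficiencies (0.75, 1, 0.75), graph mean 0.8333
  pw <- matrix(0, 3, 3); pw[1, 2] <- pw[2, 1] <- 1; pw[2, 3] <- pw[3, 2] <- 1
  dimnames(pw) <- list(letters[1:3], letters[1:3])
  path <- structure(list(weights = pw, density = 1, n_edges = 2,
                         communities = NULL, nodes = letters[1:3]),
                    class = "fc_graph")
  mp <- node_metrics(path)
  expect_equal(mp$global_efficiency, c(0.75, 1, 0.75))
  expect_equal(mean(mp$global_efficiency), (1 + 1 + 0.5) / 3)

  # star with 4 leaves: center betweenness C(4,2) = 6, leaves 0, clustering 0
  sw <- matrix(0, 5, 5); sw[1, 2:5] <- 1; sw <- sw + t(sw)
  dimnames(sw) <- list(letters[1:5], letters[1:5])
  star <- structure(list(weights = sw, density = 1, n_edges = 4,
                         communities = c("m1", "m1", "m2", "m3", "m4"),
                         nodes = letters[1:5]),
                    class = "fc_graph")
  ms <- node_metrics(star)
  expect_equal(ms$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(ms$clustering[1], 0)
  # center splits its degree evenly over 4 communities: P = 1 - 4 (1/4)^2
  expect_equal(ms$participation[1], 0.75)
  # leaves connect to a single community (m1): P = 0
  expect_equal(ms$participation[2:5], rep(0, 4))
})

test_that("all six metrics equal the brute-force oracles on random graphs", {
  set.seed(123)
  for (i in 1:12) {
    g <- random_weighted_graph(sample(5:18, 1))
    mt <- node_metrics(g)
    w <- g$weights
    d <- oracle_distances(w)
    expect_equal(mt$strength, unname(rowSums(w)), tolerance = 1e-12)
    expect_equal(mt$global_efficiency, unname(oracle_global_efficiency(w, d)),
                 tolerance = 1e-10)
    expect_equal(mt$local_efficiency, oracle_local_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(mt$clustering, oracle_clustering(w), tolerance = 1e-10)
    expect_equal(mt$betweenness, oracle_betweenness(w, d), tolerance = 1e-10)
    expect_equal(mt$participation,
                 oracle_participation(w, g$communities), tolerance = 1e-10)
  }
})

test_that("participation is bounded by 1 - 1/M with equality only for even splits", {
  m_comm <- 4
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- c(1, 1, 1, 1); w <- w + t(w)
  dimnames(w) <- list(letters[1:5], letters[1:5])
  g <- structure(list(weights = w, density = 1, n_edges = 4,
                      communities = c("x", "m1", "m2", "m3", "m4"),
                      nodes = letters[1:5]),
                 class = "fc_graph")
  mt <- node_metrics(g)
  expect_equal(mt$participation[1], 1 - 1 / m_comm)  # even split over 4 communities
  g$weights[1, 2] <- 3; g$weights[2, 1] <- 3                 # uneven split
  mt2 <- node_metrics(g)
  expect_lt(mt2$participation[1], mt$participation[1])
  # removing an edge never increases strength
  g3 <- g; g3$weights[1, 5] <- 0; g3$weights[5, 1] <- 0
  expect_true(all(node_metrics(g3)$strength <= node_metrics(g)$strength))
})

test_that("metric z-profiles use per-subject node z-scores", {
  df <- function(vals) data.frame(node = c("a", "b"), m1 = vals,
                                  m2 = c(1, 1), stringsAsFactors = FALSE)
  prof <- metric_zprofile(list(df(c(0, 2)), df(c(0, 2))), c("a", "b"))
  expect_equal(prof["a", "m1"], -sqrt(2) / 2)   # (0 - 1)/sqrt(2) with n-1 sd
  expect_equal(prof["b", "m1"], sqrt(2) / 2)
  expect_true(all(is.na(prof[, "m2"])))          # zero variance flagged
  expect_length(attr(prof, "flagged"), 2L)

  # permuting node order leaves each node's z unchanged
  d1 <- data.frame(node = c("a", "b", "c"), m1 = c(1, 5, 9))
  d2 <- d1[c(3, 1, 2), ]
  p1 <- metric_zprofile(list(d1), c("a", "c"))
  p2 <- metric_zprofile(list(d2), c("a", "c"))
  expect_equal(p1, p2)
})

test_that("gradient-topology association recovers planted monotone coupling", {
  set.seed(9)
  axis <- rnorm(100)
  mets <- data.frame(strength = rnorm(100),
                     participation = -rank(axis))
  out <- gradient_topology_association(axis, mets)
  expect_equal(out$rho[out$metric == "participation"], -1)
  expect_lt(abs(out$rho[out$metric == "strength"]), 0.3)
  expect_gt(out$q[out$metric == "strength"], 0.2)
  expect_error(gradient_topology_association(axis[1:4], mets[1:4, ]))
})
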