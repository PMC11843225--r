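test_that("bilateral averaging merges only highly correlated homolog pairs", {
  set.seed(2)
  n <- 50
  x <- rnorm(n)
  tab <- cbind(c1_g1 = x, c2_g1 = x,                 # identical homologs
               c3_g1 = rnorm(n), c4_g1 = NA,         # weakly related pair
               c5_g1 = x, c6_g1 = -x)                # sign-opposed pair
  tab[, "c4_g1"] <- 0.3 * tab[, "c3_g1"] + sqrt(1 - 0.09) * rnorm(n)
  out <- bilateral_average(tab, list(c(1, 2), c(3, 4), c(5, 6)), min_rho = 0.6)
  expect_true("c1+2_g1" %in% colnames(out))
  expect_equal(unname(out[, "c1+2_g1"]), x)
  # low correlation and negative correlation keep both columns
  expect_true(all(c("c3_g1", "c4_g1", "c5_g1", "c6_g1") %in% colnames(out)))
  log <- attr(out, "pairing")
  expect_equal(log$merged, c(TRUE, FALSE, FALSE))
  expect_equal(log$min_axis_r[3], -1)
  expect_error(bilateral_average(tab, list(c(1, 1))), "itself")
})

test_that("a pair must clear the correlation gate on every axis", {
  set.seed(5)
  n <- 40
  x <- rnorm(n)
  tab <- cbind(c1_g1 = x, c1_g2 = x, c2_g1 = x, c2_g2 = rnorm(n))
  out <- bilateral_average(tab, list(c(1, 2)), min_rho = 0.6)
  expect_false(attr(out, "pairing")$merged)
  expect_equal(ncol(out), 4L)
})

test_that("stratified folds partition subjects evenly and balance the outcome", {
  y <- rnorm(100)
  f <- stratified_folds(y, 10, seed = 3)
  expect_equal(sort(unique(f)), 0:9)
  expect_true(all(table(f) == 10))
  expect_identical(f, stratified_folds(y, 10, seed = 3))
  expect_false(identical(as.integer(f), as.integer(stratified_folds(y, 10, seed = 4))))
  # constant y degenerates to a simple random split
  fc <- stratified_folds(rep(1, 30), 5, n_bins = 1, seed = 2)
  expect_true(all(table(fc) == 6))
  expect_error(stratified_folds(rnorm(5), 10))

  # stratification reduces the spread of fold-mean y vs a single-bin split
  spread <- function(n_bins) {
    mean(vapply(1:100, function(s) {
      ff <- stratified_folds(y, 10, n_bins = n_bins, seed = 500 + s)
      var(tapply(y, ff, mean))
    }, numeric(1)))
  }
  expect_lt(spread(10), 0.5 * spread(1))
})

test_that("fold fit/eval reproduces the long-hand out-of-sample formulas", {
  set.seed(10)
  n_tr <- 20; n_te <- 10; p <- 2
  x <- matrix(rnorm((n_tr + n_te) * p), ncol = p,
              dimnames = list(NULL, c("a", "b")))
  y <- 1 + x %*% c(0.5, -0.3) + rnorm(n_tr + n_te)
  y <- as.numeric(y)
  train <- 1:n_tr; test <- n_tr + 1:n_te
  res <- fold_fit_eval(y, x, train, test)

  # independent long-hand computation
  x1 <- cbind(1, x)
  beta_or <- solve(t(x1[train, ]) %*% x1[train, ], t(x1[train, ]) %*% y[train])
  pred <- x1[test, ] %*% beta_or
  ssr <- sum((y[test] - pred)^2)
  sst <- sum((y[test] - mean(y[test]))^2)
  r2 <- 1 - ssr / sst
  f_or <- (r2 / p) / ((1 - r2) / (n_te - p - 1))
  s2 <- ssr / (n_te - p - 1)
  t_or <- beta_or[-1] / sqrt(s2 * diag(solve(t(x1[test, ]) %*% x1[test, ]))[-1])
  expect_equal(unname(res$beta), as.numeric(beta_or), tolerance = 1e-10)
  expect_equal(res$F, max(0, f_or), tolerance = 1e-10)
  expect_equal(unname(res$t), unname(t_or), tolerance = 1e-10)

  # exact linear relation: R2 = 1 and the infinite sentinel
  y2 <- as.numeric(2 + x %*% c(1, 1))
  res2 <- fold_fit_eval(y2, x, train, test)
  expect_identical(res2$F, Inf)

  # worthless model: negative out-of-sample R2 floors F at 0
  y3 <- c(rnorm(n_tr), 100 + rnorm(n_te))
  res3 <- fold_fit_eval(y3, x, train, test)
  expect_gte(res3$F, 0)
  expect_error(fold_fit_eval(y, x, 1:3, test), "train")
  expect_error(fold_fit_eval(y, x, train, n_tr + 1:3), "test")
})

test_that("cv permutation p-values hit the add-one bounds in constructed cases", {
  set.seed(30)
  n <- 80; p <- 2
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b")))
  # overwhelming effect: p at its minimum 1/(1+n_perm)
  y <- as.numeric(x %*% c(5, 0)) + 0.1 * rnorm(n)
  f <- stratified_folds(y, 5, seed = 1)
  cv <- cv_permutation_model(y, x, f, n_perm = 99, seed = 2)
  expect_equal(cv$p_F, 1 / 100)
  expect_equal(unname(cv$p_t["a"]), 1 / 100)
  expect_gt(unname(cv$mean_t["a"]), 0)

  # pure noise: p well inside the distribution
  y0 <- rnorm(n)
  cv0 <- cv_permutation_model(y0, x, stratified_folds(y0, 5, seed = 3),
                              n_perm = 199, seed = 4)
  expect_gt(cv0$p_F, 0.05)
  expect_true(all(cv0$p_t > 0.01))
  # determinism under a fixed seed
  cv0b <- cv_permutation_model(y0, x, stratified_folds(y0, 5, seed = 3),
                               n_perm = 199, seed = 4)
  expect_identical(cv0$p_F, cv0b$p_F)
  expect_identical(cv0$null_F, cv0b$null_F)
  # null pool bookkeeping: k x n_perm raw values
  expect_length(cv0$null_F, 5 * 199)
  expect_equal(dim(cv0$null_t), c(5 * 199L, 2L))
})

test_that("cv permutation p-values are calibrated under the null", {
  set.seed(77)
  n <- 60; p <- 3
  ps <- vapply(1:120, function(i) {
    y <- rnorm(n)
    x <- matrix(rnorm(n * p), n, p)
    cv <- cv_permutation_model(y, x, stratified_folds(y, 5, seed = 7000 + i),
                               n_perm = 99, seed = 8000 + i)
    cv$p_F
  }, numeric(1))
  # (super)uniformity sanity: the F-floor at 0 puts a point mass at p = 1,
  # so test one-sided against anti-conservatism (empirical CDF must not sit
  # above the uniform CDF); must not reject at alpha = 0.01
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  rate <- mean(ps < 0.05)
  expect_lt(rate, 0.15)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(11)
  for (i in 1:50) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(fdr_adjust(p), oracle_bh(p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)))
  expect_error(fdr_adjust(c(-0.1)))
})

test_that("holdout validation applies the averaged model and calibrates its null", {
  set.seed(40)
  n <- 120; p <- 2
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(x %*% c(1.5, 0)) + 0.05 * rnorm(n)
  cv <- cv_permutation_model(y, x, stratified_folds(y, 5, seed = 1),
                             n_perm = 49, seed = 2)
  xh <- matrix(rnorm(80 * p), 80, p, dimnames = list(NULL, c("a", "b")))
  yh <- as.numeric(xh %*% c(1.5, 0)) + 0.05 * rnorm(80)
  ho <- holdout_validation(cv, yh, xh, n_perm = 99, seed = 3)
  expect_equal(unname(ho$beta[-1]), unname(colMeans(cv$fold_beta)[-1]))
  expect_equal(ho$p_F, 1 / 100)   # strong effect: minimum add-one p
  expect_length(ho$null_F, 99)

  # zero averaged coefficients: F = 0 and p near 1
  cv0 <- cv
  cv0$fold_beta[] <- 0
  ho0 <- holdout_validation(cv0, yh, xh, n_perm = 99, seed = 4)
  expect_equal(ho0$F, 0)
  expect_gt(ho0$p_F, 0.5)
  expect_error(holdout_validation(cv, yh, xh[, c(2, 1)]), "match")
})

test_that("holdout recovers the sign of a planted negative effect", {
  set.seed(55)
  p <- 4
  hits <- vapply(1:20, function(i) {
    n <- 150
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- as.numeric(-0.4 * x[, 1]) + sqrt(1 - 0.16) * rnorm(n)
    cv <- cv_permutation_model(y, x, stratified_folds(y, 5, seed = 600 + i),
                               n_perm = 49, seed = 700 + i)
    nh <- 200
    xh <- matrix(rnorm(nh * p), nh, p, dimnames = list(NULL, paste0("x", 1:p)))
    yh <- as.numeric(-0.4 * xh[, 1]) + sqrt(1 - 0.16) * rnorm(nh)
    ho <- holdout_validation(cv, yh, xh, n_perm = 199, seed = 800 + i)
    unname(ho$t["x1"]) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("spearman screen matches the rank oracle and handles edge cases", {
  set.seed(14)
  x <- rnorm(50)
  tasks <- data.frame(mono = exp(x),                 # monotone transform
                      rev = -rank(x) + rnorm(50) * 0, # reversed ranks
                      rnd = rnorm(50),
                      flat = rep(1, 50))
  out <- spearman_screen(x, tasks)
  expect_equal(out$rho[out$task == "mono"], 1)
  expect_equal(out$rho[out$task == "rev"], -1)
  expect_equal(out$rho[out$task == "rnd"], oracle_spearman(x, tasks$rnd),
               tolerance = 1e-10)
  expect_true(is.na(out$rho[out$task == "flat"]))
  expect_equal(out$flag[out$task == "flat"], "constant")
  expect_true(all(out$q >= out$p - 1e-12, na.rm = TRUE))
  expect_error(spearman_screen(x[1:3], tasks[1:3, ]))
})
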