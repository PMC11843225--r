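#' Configuration for a synthetic resting-state cohort
#'
#' Bundles the parameters of the synthetic-cohort generator. The generator
#' plants K orthogonal spatial gradient maps shared by all subjects,
#' subject-specific per-vertex coordinate offsets whose standard deviation
#' follows `dispersion_profile` (heteroscedastic across vertices, creating a
#' contiguous dispersion hotspot), run-structured noisy BOLD-like time series
#' synthesized from the latent coordinates, and behavioral scores linearly
#' coupled to the planted cluster's first-gradient coordinate.
#'
#' @param n_subjects Number of subjects.
#' @param runs Integer vector of run lengths in timepoints (each >= 2);
#'   default four runs of 150, mirroring a four-run resting acquisition at
#'   toy scale.
#' @param k_latent Number of planted gradients (default 3).
#' @param gradient_maps Optional vertex x k matrix of planted orthogonal
#'   spatial patterns. When `NULL`, smooth polynomial patterns on the mesh
#'   are orthonormalized and scaled by `gradient_amplitudes`.
#' @param gradient_amplitudes Per-gradient coordinate standard deviations
#'   across vertices; strictly decreasing values make the gradient order
#'   identifiable from explained variance.
#' @param dispersion_profile Optional per-vertex cross-subject standard
#'   deviation of gradient coordinates. When `NULL`, built as
#'   `dispersion_background` everywhere and `dispersion_hotspot` inside the
#'   planted cluster.
#' @param dispersion_background,dispersion_hotspot Offset standard deviations
#'   outside/inside the planted hotspot (defaults 0.05 and 0.3).
#' @param planted_cluster Optional integer vector of hotspot vertices; when
#'   `NULL` a contiguous central patch of area `hotspot_area_mm2` is grown.
#' @param hotspot_area_mm2 Target hotspot area (default 400 mm^2, twice the
#'   200 mm^2 minimum cluster-size threshold so extraction is exercised).
#' @param behavior_effect Signed standardized slope linking the subject-level
#'   mean first-gradient coordinate over the planted cluster to the fluid
#'   intelligence score (default -0.4: a negative coupling, matching the
#'   direction of the modeled association).
#' @param covariate_effects Named numeric vector of standardized effects of
#'   age, sex, handedness, education and mean framewise displacement on the
#'   fluid latent score.
#' @param noise_sd Standard deviation of i.i.d. measurement noise added to
#'   the time series (default 1; planted signal variance is about 1.7).
#' @param smooth_window Moving-average window (timepoints) applied to the
#'   Gaussian innovations before orthonormalization, giving slow,
#'   low-frequency latent sources (default 5).
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          runs = rep(150L, 4),
                          k_latent = 3L,
                          gradient_maps = NULL,
                          gradient_amplitudes = c(1, 0.7, 0.5),
                          dispersion_profile = NULL,
                          dispersion_background = 0.05,
                          dispersion_hotspot = 0.3,
                          planted_cluster = NULL,
                          hotspot_area_mm2 = 400,
                          behavior_effect = -0.4,
                          covariate_effects = c(age = 0.1, sex = 0.1,
                                                handedness = 0,
                                                education = 0.1, fd = -0.1),
                          noise_sd = 1,
                          smooth_window = 5L,
                          seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(runs < 2)) stop("all run lengths must be >= 2")
  if (k_latent < 1) stop("k_latent must be >= 1")
  if (!is.null(dispersion_profile) && any(dispersion_profile < 0))
    stop("dispersion_profile must be nonnegative")
  if (length(gradient_amplitudes) < k_latent)
    stop("need one gradient amplitude per latent gradient")
  structure(list(
    n_subjects = as.integer(n_subjects), runs = as.integer(runs),
    k_latent = as.integer(k_latent), gradient_maps = gradient_maps,
    gradient_amplitudes = gradient_amplitudes[seq_len(k_latent)],
    dispersion_profile = dispersion_profile,
    dispersion_background = dispersion_background,
    dispersion_hotspot = dispersion_hotspot,
    planted_cluster = planted_cluster,
    hotspot_area_mm2 = hotspot_area_mm2,
    behavior_effect = behavior_effect,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd, smooth_window = as.integer(smooth_window),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Planted orthogonal gradient maps on a mesh
#'
#' Default spatial patterns: linear-in-x, linear-in-y and a saddle (x*y)
#' surface, centered, orthonormalized by QR, then scaled so gradient k has
#' coordinate standard deviation `amplitudes[k]` across vertices.
#'
#' @param mesh An `fc_mesh`.
#' @param k Number of gradients.
#' @param amplitudes Per-gradient coordinate standard deviations.
#' @return A vertex x k matrix with mutually orthogonal columns.
#' @export
planted_gradient_maps <- function(mesh, k = 3L, amplitudes = c(1, 0.7, 0.5)) {
  x <- scale(mesh$coords[, 1]); y <- scale(mesh$coords[, 2])
  basis <- cbind(x, y, x * y, x^2 - y^2, x^2 + y^2, x * y^2)
  if (k > ncol(basis)) stop("at most ", ncol(basis), " default gradients")
  basis <- scale(basis[, seq_len(k), drop = FALSE], scale = FALSE)
  q <- qr.Q(qr(basis))
  v <- nrow(q)
  g <- sweep(q, 2, amplitudes[seq_len(k)] * sqrt(v - 1), `*`)
  # sign convention: largest-magnitude element positive
  for (j in seq_len(k)) if (g[which.max(abs(g[, j])), j] < 0) g[, j] <- -g[, j]
  g
}

# smooth orthogonal latent sources for one run: moving-average-filtered
# Gaussian noise, QR-orthonormalized, scaled to ~unit temporal variance.
# Runs shorter than k cannot host k orthogonal sources; they fall back to
# centered, variance-scaled raw noise.
.latent_sources <- function(t_len, k, window) {
  x <- matrix(stats::rnorm(t_len * k), t_len, k)
  if (window >= t_len) window <- 1L
  if (window > 1) {
    f <- rep(1 / window, window)
    xs <- stats::filter(x, f, sides = 2)
    x <- ifelse(is.na(xs), x, xs)
    x <- matrix(as.numeric(x), t_len, k)
  }
  x <- scale(x, scale = FALSE)
  if (t_len > k) return(qr.Q(qr(x)) * sqrt(t_len - 1))
  sweep(x, 2, pmax(sqrt(colSums(x^2) / (t_len - 1)), 1e-12), `/`)
}

#' Simulate a synthetic cohort with planted gradient structure
#'
#' Subject s's time series at vertex v is
#' `sum_k coord(s,v,k) * source_k(t) + noise`, where
#' `coord(s,v,k) = gradient_map_k(v) + offset(s,v,k)` and the offsets are
#' Gaussian with per-vertex standard deviation given by the dispersion
#' profile. Latent sources are mutually orthogonal over time within each run
#' and shared by all subjects (one draw per run), so between-subject
#' variation lives entirely in the spatial coordinates. The fluid
#' intelligence score
#' is `behavior_effect` times the standardized subject-level mean
#' first-gradient coordinate over the planted cluster, plus covariate effects
#' and noise calibrated to unit total variance; cognitive task scores load on
#' fluid, crystallized and general latent factors so composite construction
#' can be exercised downstream.
#'
#' @param mesh An `fc_mesh`.
#' @param config A `cohort_config`.
#' @return A list of class `fc_cohort` with elements `timeseries` (list of
#'   [surface_timeseries()] objects), `behavior` (data.frame: subject id, 10
#'   task scores, covariates), `truth` (planted coordinates, cluster mask,
#'   true dispersion map, slope), `mesh`, and `config`.
#' @export
simulate_cohort <- function(mesh, config) {
  stopifnot(inherits(mesh, "fc_mesh"), inherits(config, "cohort_config"))
  v <- mesh$n_vertices
  k <- config$k_latent
  t_total <- sum(config$runs)
  if (k > min(v, t_total))
    stop("k_latent exceeds the rank bound min(n_vertices, total timepoints)")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  gmaps <- config$gradient_maps
  if (is.null(gmaps))
    gmaps <- planted_gradient_maps(mesh, k, config$gradient_amplitudes)
  if (!all(dim(gmaps) == c(v, k))) stop("gradient_maps must be vertex x k_latent")

  cluster <- config$planted_cluster
  if (is.null(cluster))
    cluster <- mesh_patch(mesh, target_area_mm2 = config$hotspot_area_mm2)
  if (length(cluster) == 0 && config$behavior_effect != 0)
    stop("planted_cluster must be nonempty when behavior_effect != 0")
  if (length(cluster) && (min(cluster) < 1 || max(cluster) > v))
    stop("planted_cluster outside the vertex set")

  disp <- config$dispersion_profile
  if (is.null(disp)) {
    disp <- rep(config$dispersion_background, v)
    disp[cluster] <- config$dispersion_hotspot
  }
  if (length(disp) != v) stop("dispersion_profile must have one entry per vertex")

  n <- config$n_subjects
  ids <- sprintf("sub%03d", seq_len(n))
  # latent temporal sources are shared by all subjects (one draw per run):
  # the between-subject structure lives entirely in the spatial coordinates
  sources <- lapply(config$runs, .latent_sources, k = k,
                    window = config$smooth_window)
  coords_true <- vector("list", n)
  names(coords_true) <- ids
  timeseries <- vector("list", n)
  names(timeseries) <- ids
  for (s in seq_len(n)) {
    offs <- matrix(stats::rnorm(v * k), v, k) * disp
    co <- gmaps + offs
    coords_true[[s]] <- co
    dat <- matrix(0, v, t_total)
    pos <- 0L
    for (ri in seq_along(config$runs)) {
      tr <- config$runs[ri]
      blk <- co %*% t(sources[[ri]])
      if (config$noise_sd > 0)
        blk <- blk + matrix(stats::rnorm(v * tr, sd = config$noise_sd), v, tr)
      dat[, pos + seq_len(tr)] <- blk
      pos <- pos + tr
    }
    timeseries[[s]] <- surface_timeseries(ids[s], dat, config$runs)
  }

  behavior <- .simulate_behavior(ids, coords_true, cluster, config)

  mask <- logical(v); mask[cluster] <- TRUE
  emb_true <- lapply(ids, function(id)
    structure(list(subject_id = id, coords = coords_true[[id]],
                   sign_flips = rep(1L, k),
                   zero_variance = rep(FALSE, k)),
              class = "fc_subject_embedding"))
  names(emb_true) <- ids
  true_disp <- if (n >= 2) vertex_dispersion(emb_true) else NULL

  structure(list(timeseries = timeseries, behavior = behavior,
                 truth = list(coords = coords_true, cluster_mask = mask,
                              planted_cluster = sort(cluster),
                              behavior_effect = config$behavior_effect,
                              dispersion_profile = disp,
                              gradient_maps = gmaps,
                              true_dispersion = true_disp,
                              embeddings = emb_true),
                 mesh = mesh, config = config),
            class = "fc_cohort")
}

# behavioral table: covariates as in a young-adult cohort, fluid latent
# coupled to the planted cluster coordinate, task scores loading on latents
.simulate_behavior <- function(ids, coords_true, cluster, config) {
  n <- length(ids)
  age <- stats::rnorm(n, 28.6, 3.6)
  sex <- stats::rbinom(n, 1, 0.5)
  # continuous laterality score in [-100, 100], skewed right-handed
  handedness <- round(pmin(100, pmax(-100, stats::rnorm(n, 66, 45))))
  education <- pmax(10, round(stats::rnorm(n, 15, 2)))
  fd <- stats::runif(n, 0.04, 0.24)

  zsafe <- function(x) if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, n)
  covz <- cbind(age = zsafe(age), sex = zsafe(sex),
                handedness = zsafe(handedness),
                education = zsafe(education), fd = zsafe(fd))
  gam <- config$covariate_effects[colnames(covz)]
  gam[is.na(gam)] <- 0

  xcl <- if (length(cluster))
    vapply(coords_true, function(co) mean(co[cluster, 1]), numeric(1))
  else rep(0, n)
  xstd <- zsafe(xcl)

  beta <- config$behavior_effect
  resid_var <- max(0.05, 1 - beta^2 - sum(gam^2))
  cov_term <- as.numeric(covz %*% gam)
  fluid_latent <- beta * xstd + cov_term +
    stats::rnorm(n, sd = sqrt(resid_var))
  cryst_latent <- 0.5 * cov_term + stats::rnorm(n, sd = sqrt(1 - min(0.9, 0.25 * sum(gam^2))))
  g_latent <- (fluid_latent + cryst_latent) / sqrt(2)

  task_of <- function(latent, loading)
    100 + 15 * (loading * latent + stats::rnorm(n, sd = sqrt(1 - loading^2)))
  w <- g_factor_weights()
  tasks <- list()
  for (tk in w$fluid) tasks[[tk]] <- task_of(fluid_latent, 0.8)
  for (tk in w$crystallized) tasks[[tk]] <- task_of(cryst_latent, 0.85)
  for (tk in setdiff(names(w$weights), c(w$fluid, w$crystallized)))
    tasks[[tk]] <- task_of(g_latent, 0.6)

  out <- data.frame(subject_id = ids, tasks[names(w$weights)],
                    age = age, sex = sex, handedness = handedness,
                    education = education, fd = fd,
                    stringsAsFactors = FALSE)
  attr(out, "cluster_coordinate") <- xcl
  out
}

#' Rank-based detection AUC for a planted vertex set
#'
#' Area under the ROC curve (Mann-Whitney form) for separating planted
#' vertices from background by a per-vertex score, used to quantify how well
#' a dispersion map recovers a planted hotspot.
#'
#' @param scores Per-vertex scores (higher = more suspect).
#' @param positive Logical mask or integer indices of the planted vertices.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, positive) {
  if (is.logical(positive)) positive <- which(positive)
  n_pos <- length(positive)
  n_neg <- length(scores) - n_pos
  if (n_pos == 0 || n_neg == 0) stop("need both planted and background vertices")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("fc_cohort: %d subjects, %d vertices, runs [%s], k=%d, planted cluster of %d vertices\n",
              length(x$timeseries), x$mesh$n_vertices,
              paste(x$config$runs, collapse = ","), x$config$k_latent,
              length(x$truth$planted_cluster)))
  invisible(x)
}
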