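#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic analysis: cohort size
#' and split, mesh geometry, embedding rank policy, dispersion thresholds,
#' cross-validation settings, and graph density. All stage seeds are derived
#' deterministically from `seed`.
#'
#' @param out_dir Output directory.
#' @param n_subjects Estimation-sample size (default 120).
#' @param n_holdout Hold-out (lockbox) sample size (default 50; together
#'   with `n_subjects`, roughly a 70/30 estimation/lockbox split).
#' @param mesh_rows,mesh_cols,edge_length_mm Mesh geometry (default 50 x 50
#'   vertices at 2 mm spacing, 9604 mm^2 of surface).
#' @param runs Run lengths in timepoints (default four runs of 75).
#' @param k Gradients to retain (default 3).
#' @param rank Per-subject component count; `NULL` = automatic (50% variance
#'   target, capped at `max_rank`).
#' @param target_variance,max_rank Automatic rank policy parameters.
#' @param percentile,min_area_mm2 Cluster extraction thresholds (defaults
#'   95th percentile, 200 mm^2).
#' @param folds,n_perm,holdout_perm Cross-validation folds (10),
#'   permutations per fold (1000), hold-out permutations (10000).
#' @param homolog_pairs List of cluster-id pairs to consider for bilateral
#'   averaging (default none; the default synthetic cohort plants a single
#'   hotspot).
#' @param min_rho Homolog-merging correlation gate (default 0.6).
#' @param density Graph density (default 0.10).
#' @param behavior_effect Planted standardized slope (default -0.4).
#' @param noise_sd Time-series noise standard deviation (default 1).
#' @param seed Master seed (default 7).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            n_subjects = 120L, n_holdout = 50L,
                            mesh_rows = 50L, mesh_cols = 50L,
                            edge_length_mm = 2,
                            runs = rep(75L, 4),
                            k = 3L, rank = NULL, target_variance = 0.5,
                            max_rank = 10L,
                            percentile = 95, min_area_mm2 = 200,
                            folds = 10L, n_perm = 1000L,
                            holdout_perm = 10000L,
                            homolog_pairs = list(), min_rho = 0.6,
                            density = 0.10,
                            behavior_effect = -0.4, noise_sd = 1,
                            seed = 7L) {
  stopifnot(n_subjects >= 2, n_holdout >= 0, k >= 1,
            percentile > 0, percentile < 100, density > 0, density <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, state_dir, resume, expr) {
  path <- file.path(state_dir, paste0(name, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  saveRDS(res, path, compress = FALSE)
  res
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> embed -> disperse -> score -> model -> graph ->
#' report. Stage results are checkpointed under `<out_dir>/state/`; with
#' `resume = TRUE`, stages whose checkpoints exist are loaded instead of
#' recomputed, so deleting a checkpoint reruns only that stage and the ones
#' after it. All outputs are plain TSV/JSON; a `manifest.json` records
#' parameters, seeds, and per-file MD5 digests so a rerun with the same
#' configuration can be verified byte for byte.
#'
#' @param config A `pipeline_config`.
#' @param resume Reuse existing stage checkpoints (default `FALSE`).
#' @return The manifest, invisibly; all results are on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  state_dir <- file.path(out, "state")
  dir.create(state_dir, recursive = TRUE, showWarnings = FALSE)

  ## simulate ----------------------------------------------------------------
  sim <- .stage("simulate", state_dir, resume, {
    mesh <- build_mesh(config$mesh_rows, config$mesh_cols,
                       config$edge_length_mm)
    cc <- cohort_config(n_subjects = config$n_subjects + config$n_holdout,
                        runs = config$runs, k_latent = config$k,
                        hotspot_area_mm2 = 2 * config$min_area_mm2,
                        behavior_effect = config$behavior_effect,
                        noise_sd = config$noise_sd,
                        seed = config$seed)
    cohort <- simulate_cohort(mesh, cc)
    est_ids <- names(cohort$timeseries)[seq_len(config$n_subjects)]
    hold_ids <- setdiff(names(cohort$timeseries), est_ids)
    list(cohort = cohort, est_ids = est_ids, hold_ids = hold_ids)
  })
  .write_tsv(sim$cohort$behavior, file.path(out, "behavior.tsv"))

  ## embed -------------------------------------------------------------------
  emb <- .stage("embed", state_dir, resume, {
    comps <- lapply(sim$cohort$timeseries, function(ts)
      subject_decomposition(normalize_concatenate(ts), r = config$rank,
                            target_variance = config$target_variance,
                            max_rank = config$max_rank))
    group <- group_decomposition(comps[sim$est_ids], k = config$k,
                                 template = sim$cohort$truth$gradient_maps)
    embs <- lapply(comps, project_subject, group = group)
    profile <- variance_profile(comps[sim$est_ids], group)
    list(components = comps, group = group, embeddings = embs,
         profile = profile)
  })
  gg <- as.data.frame(emb$group$gradients)
  names(gg) <- paste0("gradient_", seq_len(config$k))
  .write_tsv(cbind(vertex = seq_len(nrow(gg)), gg),
             file.path(out, "group_gradients.tsv"))
  .write_tsv(data.frame(component = seq_along(emb$profile$individual_fraction),
                        individual_fraction = emb$profile$individual_fraction,
                        weighted_fraction = emb$profile$weighted_fraction),
             file.path(out, "variance_profile.tsv"))

  ## disperse ----------------------------------------------------------------
  disp <- .stage("disperse", state_dir, resume, {
    dmap <- vertex_dispersion(emb$embeddings[sim$est_ids])
    axis_cor <- axis_dispersion_correlation(dmap, emb$group)
    clusters <- extract_clusters(dmap, sim$cohort$mesh,
                                 percentile = config$percentile,
                                 min_area_mm2 = config$min_area_mm2)
    if (nrow(clusters$clusters) == 0)
      stop("no clusters above threshold")
    coords_all <- cluster_coordinates(emb$embeddings, clusters)
    list(dmap = dmap, axis_cor = axis_cor, clusters = clusters,
         coords_all = coords_all)
  })
  dm <- disp$dmap
  pa <- as.data.frame(dm$per_axis); names(pa) <- paste0("axis_", seq_len(ncol(pa)))
  ce <- as.data.frame(dm$centroids); names(ce) <- paste0("centroid_", seq_len(ncol(ce)))
  .write_tsv(cbind(vertex = seq_along(dm$total), total = dm$total, pa, ce),
             file.path(out, "dispersion.tsv"))
  .write_tsv(data.frame(vertex = seq_along(disp$clusters$labels),
                        label = disp$clusters$labels),
             file.path(out, "clusters.tsv"))
  .write_tsv(disp$axis_cor, file.path(out, "axis_dispersion_correlation.tsv"))
  .write_tsv(cbind(subject_id = rownames(disp$coords_all),
                   as.data.frame(disp$coords_all)),
             file.path(out, "cluster_gradients.tsv"))

  ## score -------------------------------------------------------------------
  sc <- .stage("score", state_dir, resume, {
    beh <- sim$cohort$behavior
    scored <- data.frame(subject_id = beh$subject_id,
                         CI = composite_score(beh, "CI"),
                         FI = composite_score(beh, "FI"),
                         G = composite_score(beh, "G"))
    covs <- encode_covariates(beh)
    est <- match(sim$est_ids, beh$subject_id)
    hold <- match(sim$hold_ids, beh$subject_id)

    pairing <- NULL
    tab <- disp$coords_all
    if (length(config$homolog_pairs)) {
      tab_est <- bilateral_average(tab[est, , drop = FALSE],
                                   config$homolog_pairs, config$min_rho)
      pairing <- attr(tab_est, "pairing")
      merged <- pairing[pairing$merged, c("left", "right"), drop = FALSE]
      tab_hold <- if (nrow(merged))
        bilateral_average(tab[hold, , drop = FALSE],
                          split(as.matrix(merged), seq_len(nrow(merged))),
                          min_rho = -Inf)
      else tab[hold, , drop = FALSE]
      tab_hold <- tab_hold[, colnames(tab_est), drop = FALSE]
    } else {
      tab_est <- tab[est, , drop = FALSE]
      tab_hold <- tab[hold, , drop = FALSE]
    }

    resid_block <- function(idx, tabi) {
      y <- as.matrix(scored[idx, c("CI", "FI", "G")])
      list(y = residualize_confounds(y, covs[idx, , drop = FALSE]),
           x = residualize_confounds(tabi, covs[idx, , drop = FALSE]))
    }
    est_r <- resid_block(est, tab_est)
    hold_r <- if (length(hold)) resid_block(hold, tab_hold) else NULL
    list(scored = scored, est_r = est_r, hold_r = hold_r, pairing = pairing,
         est = est, hold = hold)
  })
  .write_tsv(sc$scored, file.path(out, "scored.tsv"))

  ## model -------------------------------------------------------------------
  mod <- .stage("model", state_dir, resume, {
    measures <- c("CI", "FI", "G")
    axes <- seq_len(config$k)
    models <- list()
    for (m in measures) for (g in axes) {
      key <- sprintf("%s_g%d", m, g)
      xcols <- grep(sprintf("_g%d$", g), colnames(sc$est_r$x), value = TRUE)
      x <- sc$est_r$x[, xcols, drop = FALSE]
      y <- sc$est_r$y[, m]
      sd_model <- config$seed + 100 + length(models)
      folds <- stratified_folds(y, config$folds, seed = sd_model)
      cv <- cv_permutation_model(y, x, folds, n_perm = config$n_perm,
                                 seed = sd_model + 1)
      ho <- if (!is.null(sc$hold_r))
        holdout_validation(cv, sc$hold_r$y[, m],
                           sc$hold_r$x[, xcols, drop = FALSE],
                           n_perm = config$holdout_perm,
                           seed = sd_model + 2)
      else NULL
      models[[key]] <- list(measure = m, axis = g, cv = cv, holdout = ho)
    }
    q_f <- fdr_adjust(vapply(models, function(mm) mm$cv$p_F, numeric(1)))
    for (i in seq_along(models)) models[[i]]$q_F <- unname(q_f[i])

    # per-task screen: first cluster's principal-gradient coordinate vs the
    # fluid-composite tasks
    g1col <- grep("_g1$", colnames(sc$est_r$x), value = TRUE)[1]
    w <- g_factor_weights()
    tasks <- sim$cohort$behavior[sc$est, w$fluid]
    task_resid <- residualize_confounds(
      as.matrix(tasks), encode_covariates(sim$cohort$behavior)[sc$est, ])
    screen <- spearman_screen(sc$est_r$x[, g1col], as.data.frame(task_resid))
    list(models = models, screen = screen, target_predictor = g1col)
  })
  model_json <- lapply(mod$models, function(mm) {
    list(measure = mm$measure, axis = mm$axis,
         fold_beta = mm$cv$fold_beta, mean_F = mm$cv$mean_F,
         mean_t = as.list(mm$cv$mean_t), p_F = mm$cv$p_F, q_F = mm$q_F,
         p_t = as.list(mm$cv$p_t), q_t = as.list(mm$cv$q_t))
  })
  jsonlite::write_json(model_json, file.path(out, "model_results.json"),
                       auto_unbox = TRUE, digits = NA)
  holdout_json <- lapply(mod$models, function(mm) {
    if (is.null(mm$holdout)) return(NULL)
    h <- mm$holdout
    list(measure = mm$measure, axis = mm$axis, beta = as.list(h$beta),
         F = h$F, p_F = h$p_F, t = as.list(h$t), p_t = as.list(h$p_t),
         q_t = as.list(h$q_t))
  })
  jsonlite::write_json(holdout_json, file.path(out, "holdout_results.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_tsv(mod$screen, file.path(out, "task_screen.tsv"))

  ## graph -------------------------------------------------------------------
  gr <- .stage("graph", state_dir, resume, {
    atlas <- synthetic_atlas(sim$cohort$mesh)
    parc <- augment_parcellation(atlas$labels, disp$clusters,
                                 atlas$communities)
    comm <- parc$parcels$community
    cluster_nodes <- parc$parcels$parcel[comm == "cluster"]
    metrics <- lapply(sim$est_ids, function(id) {
      nts <- parcel_timeseries(
        normalize_concatenate(sim$cohort$timeseries[[id]]), parc)
      g <- correlation_graph(nts, density = config$density,
                             communities = comm)
      node_metrics(g)
    })
    names(metrics) <- sim$est_ids
    zprof <- metric_zprofile(metrics, cluster_nodes)
    target <- cluster_nodes[1]
    met_target <- do.call(rbind, lapply(metrics, function(df)
      df[df$node == target, -1]))
    axis1 <- disp$coords_all[sim$est_ids, "c1_g1"]
    assoc <- gradient_topology_association(axis1, met_target)
    list(parc = parc, metrics = metrics, zprof = zprof, assoc = assoc,
         target = target)
  })
  met_long <- do.call(rbind, lapply(names(gr$metrics), function(id)
    cbind(subject_id = id, gr$metrics[[id]])))
  .write_tsv(met_long, file.path(out, "metrics.tsv"))
  .write_tsv(cbind(node = rownames(gr$zprof), gr$zprof),
             file.path(out, "zprofile.tsv"))
  .write_tsv(gr$assoc, file.path(out, "topology_association.tsv"))

  ## report ------------------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE),
                   c("manifest.json", file.path("state",
                                                list.files(file.path(out, "state")))))
  digests <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("graddisp")),
    parameters = config[setdiff(names(config), "out_dir")],
    n_clusters = nrow(disp$clusters$clusters),
    files = as.list(stats::setNames(unname(digests), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Toy grid atlas with seven-network communities
#'
#' Tiles the mesh into rectangular parcels of roughly `block` x `block`
#' vertices and assigns the seven canonical resting-state network labels
#' cyclically, providing the community structure the participation
#' coefficient needs.
#'
#' @param mesh An `fc_mesh`.
#' @param block Approximate parcel side length in vertices (default 10).
#' @return List with `labels` (per-vertex parcel name) and `communities`
#'   (named vector parcel -> network).
#' @export
synthetic_atlas <- function(mesh, block = 10L) {
  networks <- c("visual", "somatomotor", "dorsal_attention",
                "ventral_attention", "limbic", "frontoparietal", "default")
  row_of <- (seq_len(mesh$n_vertices) - 1L) %/% mesh$n_cols
  col_of <- (seq_len(mesh$n_vertices) - 1L) %% mesh$n_cols
  br <- row_of %/% block
  bc <- col_of %/% block
  idx <- br * (ceiling(mesh$n_cols / block)) + bc + 1L
  labels <- sprintf("p%03d", idx)
  parcels <- sort(unique(labels))
  communities <- stats::setNames(
    networks[(seq_along(parcels) - 1L) %% length(networks) + 1L], parcels)
  list(labels = labels, communities = communities)
}
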