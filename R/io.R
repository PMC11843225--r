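#' Write a synthetic cohort to a directory
#'
#' Layout: `cohort.json` (subject ids, dimensions, run lengths),
#' `mesh.json` (faces and vertex areas), `behavior.tsv` (one row per
#' subject), `truth.json` (planted cluster, slope, dispersion profile), and
#' one little-endian double binary array `ts_<id>.bin` (vertex x time,
#' column-major) per subject.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$timeseries)
  meta <- list(subjects = ids,
               n_vertices = cohort$mesh$n_vertices,
               runs = cohort$config$runs,
               k_latent = cohort$config$k_latent,
               seed = cohort$config$seed)
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(n_rows = cohort$mesh$n_rows,
                            n_cols = cohort$mesh$n_cols,
                            edge_length = cohort$mesh$edge_length,
                            faces = cohort$mesh$faces,
                            vertex_area = cohort$mesh$vertex_area),
                       file.path(dir, "mesh.json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted_cluster = cohort$truth$planted_cluster,
                            behavior_effect = cohort$truth$behavior_effect,
                            dispersion_profile = cohort$truth$dispersion_profile),
                       file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  for (id in ids) {
    con <- file(file.path(dir, paste0("ts_", id, ".bin")), "wb")
    writeBin(as.vector(cohort$timeseries[[id]]$data), con, size = 8,
             endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return List with `timeseries` (list of `fc_timeseries`), `behavior`
#'   (data.frame), `truth` (list), and `mesh` (an `fc_mesh` rebuilt from the
#'   stored grid dimensions).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  meshj <- jsonlite::read_json(file.path(dir, "mesh.json"),
                               simplifyVector = TRUE)
  mesh <- build_mesh(meshj$n_rows, meshj$n_cols, meshj$edge_length)
  behavior <- utils::read.delim(file.path(dir, "behavior.tsv"),
                                stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  t_total <- sum(meta$runs)
  ts <- lapply(meta$subjects, function(id) {
    con <- file(file.path(dir, paste0("ts_", id, ".bin")), "rb")
    dat <- readBin(con, "double", n = meta$n_vertices * t_total, size = 8,
                   endian = "little")
    close(con)
    surface_timeseries(id, matrix(dat, meta$n_vertices, t_total), meta$runs)
  })
  names(ts) <- meta$subjects
  list(timeseries = ts, behavior = behavior, truth = truth, mesh = mesh)
}
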