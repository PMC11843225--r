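#' Build a triangulated planar mesh
#'
#' Constructs a regular triangulated grid of `n_rows` x `n_cols` vertices with
#' spacing `edge_length_mm`, the toy stand-in for a cortical surface mesh.
#' Each grid cell is split into two triangles along the anti-diagonal, so
#' every interior vertex has six neighbors, as on a regular surface
#' triangulation. Per-vertex area is one third of the summed area of the
#' incident triangles, the usual barycentric lumping used for cluster-size
#' thresholds in mm^2.
#'
#' @param n_rows,n_cols Grid dimensions (vertices per side), both >= 2.
#' @param edge_length_mm Grid spacing in millimetres, > 0.
#'
#' @return An object of class `fc_mesh`: a list with `n_vertices`, `coords`
#'   (vertex x 2 positions in mm), `faces` (triangle x 3 vertex indices),
#'   `vertex_area` (mm^2), `neighbors` (adjacency list), and `edges`
#'   (unique undirected edge matrix, first column < second).
#'
#' @examples
#' m <- build_mesh(3, 3, 1)
#' sum(m$vertex_area)  # total area 4 mm^2
#' @export
build_mesh <- function(n_rows, n_cols, edge_length_mm = 1) {
  if (length(n_rows) != 1L || length(n_cols) != 1L || n_rows < 2 || n_cols < 2)
    stop("n_rows and n_cols must both be >= 2")
  if (edge_length_mm <= 0) stop("edge_length_mm must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  vid <- function(i, j) (i - 1L) * n_cols + j
  ij <- expand.grid(j = seq_len(n_cols), i = seq_len(n_rows))
  coords <- cbind(x = (ij$j - 1) * edge_length_mm,
                  y = (ij$i - 1) * edge_length_mm)
  n_vertices <- n_rows * n_cols

  # two triangles per cell, split along the b-c anti-diagonal
  cell <- expand.grid(j = seq_len(n_cols - 1L), i = seq_len(n_rows - 1L))
  a <- vid(cell$i, cell$j);      b <- vid(cell$i, cell$j + 1L)
  cc <- vid(cell$i + 1L, cell$j); d <- vid(cell$i + 1L, cell$j + 1L)
  faces <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  colnames(faces) <- NULL

  tri_area <- .triangle_areas(coords, faces)
  vertex_area <- numeric(n_vertices)
  for (k in 1:3) {
    acc <- rowsum(tri_area, faces[, k])
    idx <- as.integer(rownames(acc))
    vertex_area[idx] <- vertex_area[idx] + acc[, 1]
  }
  vertex_area <- vertex_area / 3

  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  neighbors <- rep(list(integer(0)), n_vertices)
  spl <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  for (nm in names(spl))
    neighbors[[as.integer(nm)]] <- sort(unique(spl[[nm]]))

  mesh <- structure(list(
    n_vertices = n_vertices, n_rows = n_rows, n_cols = n_cols,
    edge_length = edge_length_mm, coords = coords, faces = faces,
    vertex_area = vertex_area, neighbors = neighbors, edges = e
  ), class = "fc_mesh")
  stopifnot(all(vertex_area > 0), all(lengths(neighbors) >= 1))
  mesh
}

.triangle_areas <- function(coords, faces) {
  u <- coords[faces[, 2], , drop = FALSE] - coords[faces[, 1], , drop = FALSE]
  v <- coords[faces[, 3], , drop = FALSE] - coords[faces[, 1], , drop = FALSE]
  abs(u[, 1] * v[, 2] - u[, 2] * v[, 1]) / 2
}

#' Grow a contiguous vertex patch on a mesh
#'
#' Breadth-first growth from a seed vertex until the summed vertex area
#' reaches `target_area_mm2`. Used to place contiguous dispersion hotspots
#' and in tests that need connected vertex sets of known area.
#'
#' @param mesh An `fc_mesh`.
#' @param center_vertex Seed vertex index; defaults to the vertex closest to
#'   the mesh centroid.
#' @param target_area_mm2 Minimum summed vertex area of the patch.
#' @return Integer vector of vertex indices (connected under mesh adjacency).
#' @export
mesh_patch <- function(mesh, center_vertex = NULL, target_area_mm2) {
  stopifnot(inherits(mesh, "fc_mesh"), target_area_mm2 > 0)
  if (is.null(center_vertex)) {
    ctr <- colMeans(mesh$coords)
    center_vertex <- which.min((mesh$coords[, 1] - ctr[1])^2 +
                               (mesh$coords[, 2] - ctr[2])^2)
  }
  visited <- logical(mesh$n_vertices)
  patch <- integer(0)
  queue <- as.integer(center_vertex)
  visited[queue] <- TRUE
  area <- 0
  while (length(queue) && area < target_area_mm2) {
    v <- queue[1]; queue <- queue[-1]
    patch <- c(patch, v)
    area <- area + mesh$vertex_area[v]
    nb <- mesh$neighbors[[v]]
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (area < target_area_mm2)
    stop("mesh too small for requested patch area")
  sort(patch)
}

#' @export
print.fc_mesh <- function(x, ...) {
  cat(sprintf("fc_mesh: %d vertices (%d x %d grid), %d triangles, total area %.1f mm^2\n",
              x$n_vertices, x$n_rows, x$n_cols, nrow(x$faces),
              sum(.triangle_areas(x$coords, x$faces))))
  invisible(x)
}
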