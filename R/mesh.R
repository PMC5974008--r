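#' Surface mesh and point cloud containers
#'
#' `surface_mesh()` builds a validated triangle mesh: vertex coordinates in
#' millimetres, 1-based triangle indices, and per-vertex unit normals
#' (computed on construction unless supplied). Degenerate (zero-area or
#' index-repeating) triangles are dropped at load time. `point_cloud()` holds
#' an unstructured set of 3D points with optional normals, as produced by
#' intraoperative stereo reconstruction.
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param role one of `"M"` (moving/preoperative), `"T"` (target/
#'   intraoperative) or `"S"` (surface interpolated from a point cloud).
#' @param normals optional n x 3 matrix of unit vertex normals; computed by
#'   [compute_normals()] when `NULL`.
#' @param clean drop degenerate triangles before validation.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `normals`, `role`.
#' @export
surface_mesh <- function(vertices, triangles, role = "M", normals = NULL,
                         clean = TRUE) {
  vertices <- as_coord_matrix(vertices, "vertices")
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (nrow(vertices) < 3L) stop("input error: mesh needs at least 3 vertices")
  if (nrow(triangles) < 1L) stop("input error: mesh has no triangles")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("input error: triangle indices out of range")
  if (clean) {
    keep <- triangle_areas(vertices, triangles) > 1e-12 &
      triangles[, 1] != triangles[, 2] &
      triangles[, 2] != triangles[, 3] &
      triangles[, 1] != triangles[, 3]
    triangles <- triangles[keep, , drop = FALSE]
    if (nrow(triangles) == 0L)
      stop("input error: all triangles degenerate")
  }
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         normals = normals, role = role),
                    class = "surface_mesh")
  if (is.null(normals)) mesh <- compute_normals(mesh) else {
    stopifnot(nrow(normals) == nrow(vertices))
    mesh$normals <- normals
  }
  mesh
}

#' @param points numeric n x 3 matrix of coordinates (mm).
#' @rdname surface_mesh
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_coord_matrix(points, "points")
  if (nrow(points) == 0L) stop("input error: empty point cloud")
  if (!all(is.finite(points))) stop("input error: non-finite coordinates")
  structure(list(points = points, normals = normals), class = "point_cloud")
}

as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("input error: ", what, " must be n x 3")
  dimnames(x) <- NULL
  x
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh [%s]: %d vertices, %d triangles\n",
              x$role, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else " (with normals)"))
  invisible(x)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' Angle-weighted per-vertex normals
#'
#' Each vertex normal is the average of the incident face normals weighted by
#' the face's interior angle at that vertex, then normalised to unit length.
#' On a closed mesh the orientation is made globally outward (positive signed
#' volume). Isolated vertices receive a zero normal and are recorded in the
#' `isolated` attribute.
#'
#' @param mesh a [surface_mesh()].
#' @return the mesh with `normals` replaced.
#' @export
compute_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  if (nrow(f) < 1L) stop("input error: mesh has no triangles")
  # outward orientation for closed meshes: flip all faces if signed volume < 0
  if (signed_volume(v, f) < 0) {
    f <- f[, c(1L, 3L, 2L)]
    mesh$triangles <- f
  }
  fn <- face_normals(v, f)
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    i0 <- f[, k]
    i1 <- f[, k %% 3L + 1L]
    i2 <- f[, (k + 1L) %% 3L + 1L]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      pmax(sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)), 1e-300)
    ang <- acos(pmin(pmax(cosang, -1), 1))
    w <- fn * ang
    for (j in 1:3) acc[, j] <- acc[, j] + tabulate_weighted(i0, w[, j], nrow(v))
  }
  len <- sqrt(rowSums(acc^2))
  isolated <- which(len < 1e-12)
  n <- acc / pmax(len, 1e-300)
  if (length(isolated)) n[isolated, ] <- 0
  mesh$normals <- n
  attr(mesh$normals, "isolated") <- isolated
  mesh
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

signed_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Mesh summary quantities
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_area()` the total surface area (mm^2); `mean_edge_length()`
#'   the mean unique-edge length (mm); `bbox_diagonal()` the axis-aligned
#'   bounding-box diagonal (mm).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$triangles))

#' @rdname mesh_area
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh$triangles)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' @rdname mesh_area
#' @export
bbox_diagonal <- function(mesh) {
  v <- if (inherits(mesh, "point_cloud")) mesh$points else mesh$vertices
  sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
}

mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
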