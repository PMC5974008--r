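#' Fast-marching geodesic distances on a triangle mesh
#'
#' Solves the eikonal equation from a set of source vertices with a
#' first-order fast-marching scheme on the triangle mesh, giving the
#' first-arrival (shortest on-surface) distance from the nearest source to
#' every vertex. Vertices on components not connected to any source get
#' `Inf` with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param sources integer vector of 1-based source vertex indices.
#' @return an object of class `geodesic_field`: list with `sources` and
#'   `distances` (mm, one per vertex).
#' @export
geodesic_distances <- function(mesh, sources) {
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("input error: no source vertices")
  if (min(sources) < 1L || max(sources) > nrow(mesh$vertices))
    stop("input error: source index out of range")
  d <- fmm_geodesic_cpp(mesh$vertices, mesh$triangles - 1L, sources - 1L)
  if (any(!is.finite(d)))
    warning(sum(!is.finite(d)), " vertices unreachable from the sources ",
            "(disconnected component); distances reported as Inf")
  structure(list(sources = sources, distances = d), class = "geodesic_field")
}

#' Pairwise geodesic distance matrix between vertex subsets
#'
#' Runs one fast-marching sweep per `from` vertex. Used to precompute the
#' feature-to-feature and feature-to-contour distance tables.
#'
#' @param mesh a [surface_mesh()].
#' @param from,to 1-based vertex indices.
#' @return |from| x |to| matrix of distances (mm).
#' @export
geodesic_matrix <- function(mesh, from, to = from) {
  out <- matrix(NA_real_, length(from), length(to))
  for (i in seq_along(from)) {
    gf <- suppressWarnings(geodesic_distances(mesh, from[i]))
    out[i, ] <- gf$distances[to]
  }
  out
}

#' Geodesic distance from every vertex to the nearest of a vertex set
#'
#' A single multi-source fast-marching sweep; this is how features are
#' related to the ridge-line contour (distance to the nearest contour point).
#'
#' @inheritParams geodesic_matrix
#' @param set 1-based vertex indices of the set (e.g. contour vertices).
#' @return numeric vector, one distance (mm) per mesh vertex.
#' @export
geodesic_to_set <- function(mesh, set) {
  suppressWarnings(geodesic_distances(mesh, set))$distances
}

#' Snap 3D points to their nearest mesh vertices
#'
#' Euclidean nearest neighbour; ties resolve to the lowest vertex index.
#'
#' @param points n x 3 matrix of coordinates (mm).
#' @param mesh a [surface_mesh()] or [point_cloud()].
#' @return integer vector of 1-based vertex indices.
#' @export
map_to_surface <- function(points, mesh) {
  v <- if (inherits(mesh, "point_cloud")) mesh$points else mesh$vertices
  points <- as_coord_matrix(points, "points")
  as.integer(nn_index_cpp(points, v))
}
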