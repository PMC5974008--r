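#' Estimate oriented normals for a point cloud
#'
#' Per-point PCA over the `k` nearest neighbours gives the normal direction;
#' orientation is made globally consistent by flipping along a breadth-first
#' traversal of the neighbour graph, then (for roughly closed clouds) made
#' outward with respect to the centroid majority.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbourhood size.
#' @return the cloud with `normals` filled in.
#' @export
estimate_cloud_normals <- function(cloud, k = 12L) {
  p <- cloud$points
  n <- nrow(p)
  if (n < 3L) stop("reconstruction error: too few points")
  k <- min(k, n - 1L)
  nb <- knn_index_cpp(p, p, k + 1L)[, -1, drop = FALSE]
  nrm <- matrix(0, n, 3)
  planar <- 0
  for (i in seq_len(n)) {
    q <- p[c(i, nb[i, ]), , drop = FALSE]
    q <- sweep(q, 2, colMeans(q))
    sv <- svd(q, nu = 0, nv = 3)
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) planar <- planar + 1
    nrm[i, ] <- sv$v[, 3]
  }
  if (planar == n) stop("reconstruction error: degenerate (collinear) cloud")
  # orientation propagation over the kNN graph
  visited <- logical(n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    for (j in nb[i, ]) {
      if (!visited[j]) {
        if (sum(nrm[i, ] * nrm[j, ]) < 0) nrm[j, ] <- -nrm[j, ]
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (any(!visited)) {  # disconnected patches: orient each by centroid
    for (i in which(!visited))
      if (sum(nrm[i, ] * (p[i, ] - colMeans(p))) < 0) nrm[i, ] <- -nrm[i, ]
  }
  if (sum(rowSums(nrm * sweep(p, 2, colMeans(p)))) < 0) nrm <- -nrm
  cloud$normals <- nrm
  cloud
}

#' Interpolate a triangulated surface through a point cloud
#'
#' Builds the smooth interpolated surface S used to compute geodesics when
#' the intraoperative target is a sparse point cloud. Each point's nearest
#' neighbours are projected into its tangent plane and fan-triangulated in
#' angular order; triangles supported by at least two of their corners are
#' kept. Vertices of S are exactly the input points, so S passes through the
#' cloud; edges longer than `max_edge_factor` times the median neighbour
#' spacing are rejected, which keeps open boundaries open and disconnected
#' stereo patches disconnected.
#'
#' @param cloud a [point_cloud()] with at least 50 points.
#' @param k neighbourhood size for the local triangulation.
#' @param max_edge_factor edge-length cutoff as a multiple of the median
#'   nearest-neighbour spacing.
#' @return a [surface_mesh()] with role `"S"`.
#' @export
reconstruct_surface <- function(cloud, k = 10L, max_edge_factor = 4) {
  p <- cloud$points
  n <- nrow(p)
  if (n < 50L) stop("reconstruction error: need at least 50 points")
  if (is.null(cloud$normals)) cloud <- estimate_cloud_normals(cloud, k = max(k, 12L))
  nrm <- cloud$normals
  k <- min(k, n - 1L)
  nb <- knn_index_cpp(p, p, k + 1L)[, -1, drop = FALSE]
  d1 <- sqrt(rowSums((p[nb[, 1], , drop = FALSE] - p)^2))
  max_edge <- max_edge_factor * median(d1)

  tris <- vector("list", n)
  for (i in seq_len(n)) {
    z <- nrm[i, ]
    x <- c(1, 0, 0)
    if (abs(sum(x * z)) > 0.9) x <- c(0, 1, 0)
    x <- x - sum(x * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
    rel <- sweep(p[nb[i, ], , drop = FALSE], 2, p[i, ])
    len <- sqrt(rowSums(rel^2))
    ok <- len <= max_edge & len > 0
    if (sum(ok) < 2L) next
    jn <- nb[i, ok]
    ang <- atan2(rel[ok, , drop = FALSE] %*% y, rel[ok, , drop = FALSE] %*% x)
    ord <- order(ang)
    jn <- jn[ord]
    ang <- ang[ord]
    m <- length(jn)
    gaps <- c(diff(ang), 2 * pi - (ang[m] - ang[1]))
    keep <- gaps < (100 * pi / 180)  # angular gap => boundary, no fan across it
    a <- jn
    b <- jn[c(2:m, 1)]
    sel <- keep & sqrt(rowSums((p[a, , drop = FALSE] - p[b, , drop = FALSE])^2)) <= max_edge
    if (any(sel)) tris[[i]] <- cbind(i, a[sel], b[sel])
  }
  tri <- do.call(rbind, tris)
  if (is.null(tri) || nrow(tri) == 0L)
    stop("reconstruction error: no triangles could be formed")
  # canonical key ignoring orientation; keep triangles proposed by >= 2 corners
  key <- apply(tri, 1, function(r) paste(sort(r), collapse = "-"))
  cnt <- table(key)
  keep_keys <- names(cnt)[cnt >= 2]
  tri <- tri[match(keep_keys, key), , drop = FALSE]
  if (nrow(tri) == 0L) stop("reconstruction error: triangulation unsupported")
  # orient each triangle with the local normal
  fn <- face_normals(p, tri)
  flip <- rowSums(fn * nrm[tri[, 1], , drop = FALSE]) < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2), drop = FALSE]
  mesh <- surface_mesh(p, tri, role = "S")
  mesh$normals <- nrm  # keep cloud normals: orientation independent of closure
  mesh
}
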