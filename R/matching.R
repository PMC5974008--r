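#' Pairwise geodesic-consistency measures
#'
#' `geodesic_consistency()` compares a geodesic distance measured on the
#' moving surface with the corresponding distance on the target surface as
#' the ratio `min(dg_m / (dg_t + eps), dg_t / (dg_m + eps))`, which lies in
#' [0, 1], equals ~1 when the two distances agree (the pair of
#' correspondences is geometrically consistent) and is symmetric and
#' scale-invariant up to `eps`. `rigidity_kernel()` maps a consistency value
#' through a Gaussian centred at 1, `exp(-(c - 1)^2 / (2 sigma^2))`; `sigma`
#' sets how much non-rigid deviation from perfect isometry is tolerated.
#'
#' @param dg_m,dg_t non-negative geodesic distances (mm) on the moving and
#'   target surfaces (vectorised).
#' @param eps small positive ratio guard (mm).
#' @return values in [0, 1].
#' @export
geodesic_consistency <- function(dg_m, dg_t, eps = 1e-8) {
  if (any(dg_m < 0) || any(dg_t < 0)) stop("input error: negative distance")
  if (eps <= 0) stop("input error: eps must be > 0")
  pmin(dg_m / (dg_t + eps), dg_t / (dg_m + eps))
}

#' @param c consistency values in [0, 1].
#' @param sigma positive non-rigidity bandwidth (dimensionless).
#' @rdname geodesic_consistency
#' @export
rigidity_kernel <- function(c, sigma) {
  if (sigma <= 0) stop("input error: sigma must be > 0")
  exp(-(c - 1)^2 / (2 * sigma^2))
}

#' Contour (ridge-line) consistency term
#'
#' The contour constraint for a pair of candidate correspondences i and j:
#' each candidate contributes the rigidity kernel of the consistency between
#' its feature-to-contour geodesic distances on the two surfaces, and the
#' pair term is the average of the two, so it is symmetric in i and j.
#'
#' @param bm_i,bt_i distance (mm) of candidate i's features to the nearest
#'   contour point on the moving / target surface.
#' @param bm_j,bt_j same for candidate j.
#' @param sigma_b contour bandwidth.
#' @param eps ratio guard.
#' @return value in (0, 1].
#' @export
contour_term <- function(bm_i, bt_i, bm_j, bt_j, sigma_b = 0.3, eps = 1e-8) {
  gi <- rigidity_kernel(geodesic_consistency(bm_i, bt_i, eps), sigma_b)
  gj <- rigidity_kernel(geodesic_consistency(bm_j, bt_j, eps), sigma_b)
  (gi + gj) / 2
}

#' Descriptor similarity
#'
#' Gaussian of the L2 descriptor distance, `exp(-dist^2 / (2 sigma_f^2))`.
#' The bandwidth defaults to the median candidate descriptor distance
#' (median heuristic), floored at 1e-8 so identical descriptor sets do not
#' degenerate.
#'
#' @param dist non-negative descriptor distances.
#' @param sigma_f bandwidth; computed from `dist` when `NULL`.
#' @return similarities in [0, 1], monotone decreasing in `dist`.
#' @export
descriptor_similarity <- function(dist, sigma_f = NULL) {
  if (any(dist < 0)) stop("input error: negative distance")
  if (is.null(sigma_f)) sigma_f <- max(median(dist), 1e-8)
  exp(-dist^2 / (2 * sigma_f^2))
}

#' Affinity-matrix parameters
#'
#' Defaults are the operating point used throughout: `sigma_d = sigma_b =
#' 0.3`, `alpha = 0.6`, `eps = 1e-8`. `alpha = 1` removes the contour term
#' entirely (geodesic consistency only).
#'
#' @param sigma_d geodesic-consistency bandwidth (> 0).
#' @param sigma_b contour bandwidth (> 0).
#' @param alpha mixing weight in [0, 1] between the geodesic and contour
#'   pairwise terms.
#' @param eps ratio guard (mm).
#' @return a list of class `affinity_params`.
#' @export
affinity_params <- function(sigma_d = 0.3, sigma_b = 0.3, alpha = 0.6,
                            eps = 1e-8) {
  if (sigma_d <= 0 || sigma_b <= 0) stop("input error: sigma must be > 0")
  if (alpha < 0 || alpha > 1) stop("input error: alpha must be in [0, 1]")
  if (eps <= 0) stop("input error: eps must be > 0")
  structure(list(sigma_d = sigma_d, sigma_b = sigma_b, alpha = alpha,
                 eps = eps), class = "affinity_params")
}

#' Build the contour-constrained affinity matrix
#'
#' One node per candidate correspondence. Diagonal entries are the
#' descriptor similarities; off-diagonal entries mix the geodesic-distance
#' consistency kernel with the contour consistency term,
#' `alpha * g + (1 - alpha) * g_b`. Candidates sharing a moving or target
#' feature are conflicting assignments and get affinity 0, as do pairs whose
#' geodesic distances are not finite (disconnected patches).
#'
#' @param C a `correspondence_set` (stage `"C"`).
#' @param dg_m,dg_t geodesic distance matrices (mm) between moving features
#'   and between target features, indexed by feature position.
#' @param b_m,b_t per-feature geodesic distance (mm) to the nearest contour
#'   point on each surface; may be `NULL` when `alpha = 1`.
#' @param params an [affinity_params()].
#' @return symmetric matrix with entries in [0, 1], attribute `"sim"` =
#'   diagonal unary similarities.
#' @export
build_affinity <- function(C, dg_m, dg_t, b_m = NULL, b_t = NULL,
                           params = affinity_params()) {
  pairs <- C$pairs
  n <- nrow(pairs)
  sim <- descriptor_similarity(pairs$dist)
  DM <- dg_m[pairs$m, pairs$m, drop = FALSE]
  DT <- dg_t[pairs$t, pairs$t, drop = FALSE]
  if (!all(dim(DM) == c(n, n)) || !all(dim(DT) == c(n, n)))
    stop("input error: geodesic matrix dimensions do not match candidates")
  cons <- geodesic_consistency(pmax(DM, 0), pmax(DT, 0), params$eps)
  g <- rigidity_kernel(cons, params$sigma_d)
  if (params$alpha < 1) {
    if (is.null(b_m) || is.null(b_t))
      stop("missing contour: supply ridge-line contours on both surfaces ",
           "(or set alpha = 1 to drop the contour term)")
    gb1 <- rigidity_kernel(
      geodesic_consistency(b_m[pairs$m], b_t[pairs$t], params$eps),
      params$sigma_b)
    GB <- (outer(gb1, rep(1, n)) + outer(rep(1, n), gb1)) / 2
    W <- params$alpha * g + (1 - params$alpha) * GB
  } else {
    W <- g
  }
  # conflicting assignments (shared moving or target feature) must not
  # reinforce each other; non-finite geodesics (disconnected) carry no support
  conflict <- outer(pairs$m, pairs$m, `==`) | outer(pairs$t, pairs$t, `==`)
  W[conflict] <- 0
  W[!is.finite(DM) | !is.finite(DT)] <- 0
  diag(W) <- sim
  W[!is.finite(W)] <- 0
  attr(W, "sim") <- sim
  W
}

#' Principal eigenvector by power iteration
#'
#' Deterministic all-ones start, tolerance 1e-8, at most 10000 iterations.
#' For a non-negative matrix the result is the (entrywise non-negative)
#' Perron vector.
#'
#' @param W square non-negative matrix.
#' @return unit vector.
#' @export
principal_eigenvector <- function(W, tol = 1e-8, max_iter = 10000L) {
  n <- nrow(W)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(W %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(rep(0, n))
    y <- y / ny
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  x
}

#' Spectral pruning of candidate correspondences
#'
#' Extracts the dominant geometrically-consistent cluster from the affinity
#' matrix: candidates are ranked by their component of the principal
#' eigenvector of `W` and accepted greedily, rejecting any candidate that
#' conflicts (shares a moving or target feature) with one already accepted.
#' Acceptance stops when the next candidate's eigenvector component falls
#' below `min_component` times the maximum, or when adding it would decrease
#' the cluster coherence `x'Wx / |x|^2` of the accepted set (the binary
#' Rayleigh quotient), whichever comes first. The result is one-to-one in
#' both feature sets.
#'
#' Acceptance additionally stops after `max_pairs` candidates: correct
#' correspondences concentrate at the top of the eigenvector ranking, the
#' rigid estimation only needs a handful of pairs, and a small pruned set is
#' the operating regime the downstream RANSAC acceptance thresholds assume
#' (on liver data the useful set is roughly a dozen pairs).
#'
#' @param W affinity matrix from [build_affinity()].
#' @param C the `correspondence_set` whose candidates index `W`.
#' @param min_component relative eigenvector threshold.
#' @param max_pairs acceptance cap (`Inf` to disable).
#' @return a `correspondence_set` with stage `"C_p"` and an `eigen_score`
#'   column; empty (with a warning) when `W` is all zero.
#' @export
spectral_prune <- function(W, C, min_component = 1e-3, max_pairs = 20L) {
  pairs <- C$pairs
  n <- nrow(pairs)
  if (n == 0L) stop("input error: empty candidate set")
  x <- principal_eigenvector(W)
  if (all(x == 0) || all(W == 0)) {
    warning("all-zero affinity matrix: no consistent correspondences")
    out <- C
    out$pairs <- pairs[0, ]
    out$stage <- "C_p"
    return(out)
  }
  x <- abs(x)
  ord <- order(x, decreasing = TRUE)
  xmax <- x[ord[1]]
  accepted <- integer(0)
  used_m <- integer(0)
  used_t <- integer(0)
  S <- 0  # sum of W over the accepted block = x'Wx for binary x
  for (i in ord) {
    if (length(accepted) >= max_pairs) break
    if (x[i] < min_component * xmax) break
    if (pairs$m[i] %in% used_m || pairs$t[i] %in% used_t) next
    S_new <- S + W[i, i] + if (length(accepted)) 2 * sum(W[i, accepted]) else 0
    k <- length(accepted)
    if (k > 0 && S_new / (k + 1) <= S / k) break
    accepted <- c(accepted, i)
    used_m <- c(used_m, pairs$m[i])
    used_t <- c(used_t, pairs$t[i])
    S <- S_new
  }
  out <- C
  out$pairs <- pairs[accepted, , drop = FALSE]
  out$pairs$eigen_score <- x[accepted]
  rownames(out$pairs) <- NULL
  out$stage <- "C_p"
  out
}

#' Quadratic-assignment energy of a correspondence set (diagnostic)
#'
#' The raw matching energy: total descriptor distance plus the squared
#' differences of all pairwise geodesic distances. Never optimised directly
#' (the affinity/spectral formulation replaces it); exposed to compare
#' correspondence sets.
#'
#' @inheritParams build_affinity
#' @return a single number (lower = better).
#' @export
qap_energy <- function(C, dg_m, dg_t) {
  pairs <- C$pairs
  DM <- dg_m[pairs$m, pairs$m, drop = FALSE]
  DT <- dg_t[pairs$t, pairs$t, drop = FALSE]
  sum(pairs$dist) + sum((DM - DT)^2)
}

#' Export a correspondence set to CSV
#'
#' @param C a `correspondence_set`.
#' @param path output file.
#' @export
write_correspondences <- function(C, path) {
  write.csv(C$pairs, path, row.names = FALSE)
  invisible(path)
}

# distance from each point to the surface near its snapped vertex
# (exact point-to-triangle distance over the vertex's incident faces)
point_to_mesh_distance <- function(points, mesh, idx) {
  vapply(seq_len(nrow(points)), function(i) {
    faces <- which(mesh$triangles[, 1] == idx[i] |
                   mesh$triangles[, 2] == idx[i] |
                   mesh$triangles[, 3] == idx[i])
    if (!length(faces))
      return(sqrt(sum((points[i, ] - mesh$vertices[idx[i], ])^2)))
    min(vapply(faces, function(f)
      point_triangle_distance(points[i, ],
                              mesh$vertices[mesh$triangles[f, 1], ],
                              mesh$vertices[mesh$triangles[f, 2], ],
                              mesh$vertices[mesh$triangles[f, 3], ]),
      numeric(1)))
  }, numeric(1))
}

point_triangle_distance <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c_
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c_ - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

#' Snap an ordered contour polyline to a surface
#'
#' Maps the delineated ridge-line points to mesh vertices and computes the
#' geodesic distance field to the contour (distance from every vertex to its
#' nearest contour vertex), used by the contour affinity term.
#'
#' @param mesh a [surface_mesh()].
#' @param points ordered n x 3 contour points (mm), same frame as the mesh.
#' @param max_snap error if any contour point is farther than this (mm) from
#'   the surface.
#' @return class `contour_set`: `vertices` (snapped, deduplicated, in input
#'   order), `points`, `field` (per-vertex distance to the contour, mm).
#' @export
contour_set <- function(mesh, points, max_snap = 5) {
  points <- as_coord_matrix(points, "contour points")
  idx <- map_to_surface(points, mesh)
  snap_err <- point_to_mesh_distance(points, mesh, idx)
  if (any(snap_err > max_snap))
    stop("input error: contour point ", which.max(snap_err), " is ",
         sprintf("%.1f", max(snap_err)), " mm from the surface (limit ",
         max_snap, " mm)")
  idx <- idx[!duplicated(idx)]
  structure(list(vertices = idx, points = points,
                 field = geodesic_to_set(mesh, idx)),
            class = "contour_set")
}
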