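#' Farthest point sampling of mesh vertices
#'
#' Iteratively adds the vertex (inside the visibility mask, if any) that
#' maximises the distance to the already-selected set, giving uniform
#' coverage of the surface. Euclidean distances by default; on-surface
#' (geodesic) distances behind `geodesic = TRUE`.
#'
#' @param mesh a [surface_mesh()] or [point_cloud()].
#' @param n number of feature vertices.
#' @param mask optional integer vector of candidate vertex indices (the
#'   intraoperatively visible part of the moving surface); default all.
#' @param seed integer; selects the starting vertex deterministically.
#' @param geodesic use fast-marching distances instead of Euclidean.
#' @param start optional explicit starting vertex (overrides the seeded
#'   choice).
#' @return an object of class `feature_set`: list with `indices` (1-based
#'   vertex ids), `strategy`, `mask`.
#' @export
farthest_point_sampling <- function(mesh, n, mask = NULL, seed = 1L,
                                    geodesic = FALSE, start = NULL) {
  v <- if (inherits(mesh, "point_cloud")) mesh$points else mesh$vertices
  if (is.null(mask)) mask <- seq_len(nrow(v))
  mask <- unique(as.integer(mask))
  if (n < 1L || n > length(mask))
    stop("input error: n must be in [1, |mask|]")
  set.seed(seed)
  if (is.null(start)) start <- mask[sample.int(length(mask), 1L)]
  if (!start %in% mask) stop("input error: start vertex not in mask")
  chosen <- integer(n)
  chosen[1L] <- start
  if (geodesic && !inherits(mesh, "point_cloud")) {
    mind <- suppressWarnings(geodesic_distances(mesh, start))$distances[mask]
    for (i in seq_len(n - 1L)) {
      nxt <- mask[which.max(mind)]
      chosen[i + 1L] <- nxt
      mind <- pmin(mind,
                   suppressWarnings(geodesic_distances(mesh, nxt))$distances[mask])
    }
  } else {
    vm <- v[mask, , drop = FALSE]
    mind <- sqrt(rowSums(sweep(vm, 2, v[start, ])^2))
    for (i in seq_len(n - 1L)) {
      nxt_local <- which.max(mind)
      chosen[i + 1L] <- mask[nxt_local]
      mind <- pmin(mind, sqrt(rowSums(sweep(vm, 2, vm[nxt_local, ])^2)))
    }
  }
  structure(list(indices = chosen, strategy = "fps", mask = mask),
            class = "feature_set")
}

#' Normal-space sampling of mesh vertices
#'
#' Buckets vertex normals on a sphere grid and draws samples round-robin
#' from the occupied buckets, so normal directions are represented as evenly
#' as possible and flat regions contribute few points.
#'
#' @inheritParams farthest_point_sampling
#' @param bins number of azimuthal subdivisions of the normal sphere; the
#'   grid has roughly `bins^2 / 2` cells.
#' @return a `feature_set`.
#' @export
normal_space_sampling <- function(mesh, n, bins = 8L, mask = NULL, seed = 1L) {
  if (bins < 1L) stop("input error: bins must be >= 1")
  if (n < 0L) stop("input error: n must be >= 0")
  if (is.null(mask)) mask <- seq_len(nrow(mesh$vertices))
  mask <- unique(as.integer(mask))
  if (n > length(mask)) stop("input error: n exceeds available vertices")
  out <- structure(list(indices = integer(0), strategy = "normal_space",
                        mask = mask), class = "feature_set")
  if (n == 0L) return(out)
  nrm <- mesh$normals[mask, , drop = FALSE]
  theta <- acos(pmin(pmax(nrm[, 3], -1), 1))          # [0, pi]
  phi <- atan2(nrm[, 2], nrm[, 1]) + pi               # [0, 2pi]
  cell <- pmin(floor(theta / pi * bins), bins - 1L) * (2L * bins) +
    pmin(floor(phi / (2 * pi) * (2L * bins)), 2L * bins - 1L)
  set.seed(seed)
  buckets <- split(mask, cell)
  buckets <- lapply(buckets, function(b) b[sample.int(length(b))])
  buckets <- buckets[sample.int(length(buckets))]
  # each bucket's share is capped at ceiling(n / #occupied buckets), so flat
  # regions (one big bucket) cannot dominate; fewer than n samples may be
  # returned when the cap binds
  max_share <- ceiling(n / length(buckets))
  chosen <- integer(0)
  round_i <- 1L
  while (length(chosen) < n && round_i <= max_share) {
    added <- FALSE
    for (b in buckets) {
      if (length(b) >= round_i) {
        chosen <- c(chosen, b[round_i])
        added <- TRUE
        if (length(chosen) == n) break
      }
    }
    if (!added) break
    round_i <- round_i + 1L
  }
  out$indices <- chosen
  out
}

#' TOLDI local 3D shape descriptor
#'
#' Triple Orthogonal Local Depth Images. For each feature vertex a local
#' reference frame (LRF) is built from the support neighbourhood (all
#' vertices within `radius`): the z-axis is the smallest-scatter direction of
#' the distance-weighted covariance about the feature point, sign-flipped so
#' it points to the outside of the surface; the x-axis is the weighted sum of
#' the support vectors projected into the tangent plane (TOLDI's
#' sign-disambiguated construction); y completes the right-handed frame.
#' Support points expressed in the LRF are rendered into three orthogonal
#' `L` x `L` depth images (views along z, x and y) which are concatenated
#' into a `3 L^2` vector with entries in [0, 1] (1 = empty pixel).
#' The descriptor is invariant to rigid transformations by construction.
#'
#' @param mesh a [surface_mesh()] or [point_cloud()].
#' @param features a `feature_set` or integer vertex indices.
#' @param radius support radius in mm; default 15% of the bounding-box
#'   diagonal.
#' @param L depth-image width in pixels.
#' @return an object of class `descriptor_set`: `vectors` (one row per
#'   feature, `3 L^2` columns), `indices`, `valid` (features with fewer than
#'   5 support points are flagged invalid and excluded from matching),
#'   `radius`, `L`.
#' @export
compute_toldi <- function(mesh, features, radius = NULL, L = 20L) {
  idx <- if (inherits(features, "feature_set")) features$indices else as.integer(features)
  v <- if (inherits(mesh, "point_cloud")) mesh$points else mesh$vertices
  if (is.null(radius)) radius <- 0.15 * bbox_diagonal(mesh)
  if (radius <= 0) stop("input error: radius must be > 0")
  if (L < 2L) stop("input error: L must be >= 2")
  nf <- length(idx)
  desc <- matrix(1, nf, 3L * L * L)
  valid <- logical(nf)
  for (i in seq_len(nf)) {
    p <- v[idx[i], ]
    rel <- sweep(v, 2, p)
    d2 <- rowSums(rel^2)
    sup <- which(d2 <= radius^2 & d2 > 0)
    if (length(sup) < 5L) next
    rel <- rel[sup, , drop = FALSE]
    d <- sqrt(d2[sup])
    lrf <- toldi_lrf(rel, d, radius)
    if (is.null(lrf)) next
    q <- rel %*% lrf  # columns: x, y, z coordinates in the LRF
    desc[i, ] <- c(depth_image(q[, 1], q[, 2], q[, 3], radius, L),  # view along z
                   depth_image(q[, 2], q[, 3], q[, 1], radius, L),  # view along x
                   depth_image(q[, 3], q[, 1], q[, 2], radius, L))  # view along y
    valid[i] <- TRUE
  }
  structure(list(vectors = desc, indices = idx, valid = valid,
                 radius = radius, L = as.integer(L)),
            class = "descriptor_set")
}

# LRF columns (x, y, z); rel = support points relative to the feature
toldi_lrf <- function(rel, d, radius) {
  w <- (radius - d)^2
  cov <- crossprod(rel * sqrt(w))
  eg <- eigen(cov, symmetric = TRUE)
  z <- eg$vectors[, 3]
  if (sum(rel %*% z) > 0) z <- -z  # outward: support lies below the tangent plane
  proj <- rel - (rel %*% z) %*% t(z)
  w2 <- as.numeric(rel %*% z)^2
  vx <- colSums(proj * (w * w2))
  nx <- sqrt(sum(vx^2))
  if (nx < 1e-12) return(NULL)  # rotationally symmetric support: no stable x-axis
  x <- vx / nx
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

# depth image for the view looking along `depth` axis; u, v span the image
depth_image <- function(u, v, depth, radius, L) {
  img <- matrix(1, L, L)
  iu <- pmin(pmax(floor((u + radius) / (2 * radius) * L), 0), L - 1) + 1
  iv <- pmin(pmax(floor((v + radius) / (2 * radius) * L), 0), L - 1) + 1
  dep <- pmin(pmax((depth + radius) / (2 * radius), 0), 1)
  ord <- order(dep, decreasing = TRUE)  # nearest point (smallest depth) wins
  img[cbind(iu[ord], iv[ord])] <- dep[ord]
  as.numeric(img)
}

#' Candidate correspondences by descriptor k-nearest neighbours
#'
#' For every valid target feature, the `k` moving features with the closest
#' TOLDI descriptors (Euclidean distance) become candidate pairs; this is
#' the initial correspondence set C handed to spectral pruning.
#'
#' @param desc_m,desc_t `descriptor_set`s of the moving and target surfaces.
#' @param k neighbours per target feature; clamped to the number of valid
#'   moving features.
#' @return an object of class `correspondence_set`: data.frame with columns
#'   `m` (moving feature position), `t` (target feature position),
#'   `m_vertex`, `t_vertex`, `dist` (descriptor distance); `stage = "C"`.
#' @export
candidate_correspondences <- function(desc_m, desc_t, k = 5L) {
  if (k < 1L) stop("input error: k must be >= 1")
  vm <- which(desc_m$valid)
  vt <- which(desc_t$valid)
  if (length(vm) == 0L || length(vt) == 0L)
    stop("input error: empty descriptor set")
  k <- min(k, length(vm))
  A <- desc_m$vectors[vm, , drop = FALSE]
  B <- desc_t$vectors[vt, , drop = FALSE]
  d2 <- outer(rowSums(B^2), rowSums(A^2), `+`) - 2 * B %*% t(A)
  d2[d2 < 0] <- 0
  rows <- lapply(seq_along(vt), function(j) {
    ord <- order(d2[j, ])[seq_len(k)]
    data.frame(m = vm[ord], t = vt[j], dist = sqrt(d2[j, ord]))
  })
  pairs <- do.call(rbind, rows)
  pairs$m_vertex <- desc_m$indices[pairs$m]
  pairs$t_vertex <- desc_t$indices[pairs$t]
  structure(list(pairs = pairs[, c("m", "t", "m_vertex", "t_vertex", "dist")],
                 stage = "C"), class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("correspondence_set [%s]: %d pairs\n", x$stage, nrow(x$pairs)))
  invisible(x)
}
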