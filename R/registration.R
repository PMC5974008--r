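#' Rigid transform container
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector (mm).
#' @return class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("input error: rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation %.2f mm\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

rotation_angle <- function(R) acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))

#' Apply, invert and compose rigid transforms
#'
#' @param transform a [rigid_transform()].
#' @param x n x 3 points, a [surface_mesh()] or a [point_cloud()].
#' @return transformed points / object; `invert_transform()` the inverse
#'   transform; `compose_transforms(a, b)` the transform "b then a".
#' @export
apply_transform <- function(transform, x) {
  tf <- function(p) sweep(p %*% t(transform$rotation), 2,
                          -transform$translation)
  if (inherits(x, "surface_mesh")) {
    x$vertices <- tf(x$vertices)
    x$normals <- x$normals %*% t(transform$rotation)
    x
  } else if (inherits(x, "point_cloud")) {
    x$points <- tf(x$points)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$rotation)
    x
  } else tf(as_coord_matrix(x, "points"))
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' @param a,b [rigid_transform()]s.
#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid transform between paired points
#'
#' Closed-form Kabsch/Umeyama solution: minimises
#' `sum ||R src_i + t - dst_i||^2` via SVD of the cross-covariance, with the
#' determinant correction that prevents reflections. Samples whose centred
#' source points are (near-)collinear are rejected, since the in-plane
#' rotation is then unconstrained.
#'
#' @param src,dst n x 3 matrices of paired points (mm), n >= 3.
#' @return a [rigid_transform()].
#' @export
estimate_rigid <- function(src, dst) {
  src <- as_coord_matrix(src, "src")
  dst <- as_coord_matrix(dst, "dst")
  if (nrow(src) < 3L || nrow(src) != nrow(dst))
    stop("degenerate sample: need >= 3 point pairs")
  cs <- colMeans(src)
  cd <- colMeans(dst)
  A <- sweep(src, 2, cs)
  B <- sweep(dst, 2, cd)
  sv_a <- svd(A, nu = 0, nv = 0)$d
  if (sv_a[2] < 1e-6 * sv_a[1])
    stop("degenerate sample: collinear points")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(cd - R %*% cs))
}

#' RANSAC parameters
#'
#' @param max_iter iteration cap.
#' @param d_ransac RMSE acceptance threshold (mm): 5 for the rigid synthetic
#'   benchmark, 10 otherwise.
#' @param a_normals normal-angle acceptance threshold (degrees).
#' @param seed RNG seed (sampling of minimal subsets).
#' @param refit re-estimate the final transform on its inlier pairs.
#' @param score best-model selection rule: `"consensus"` (most pairs within
#'   `d_ransac`, RMSE tie-break; robust to gross outliers in the pruned
#'   set) or `"rmse"` (smallest RMSE over the whole set, the selection the
#'   fallback rule of the original protocol describes; adequate when the
#'   pruned set is small and mostly correct).
#' @return class `ransac_params`.
#' @export
ransac_params <- function(max_iter = 1000L, d_ransac = 10, a_normals = 60,
                          seed = 1L, refit = TRUE,
                          score = c("consensus", "rmse")) {
  score <- match.arg(score)
  if (max_iter < 1L) stop("input error: max_iter must be >= 1")
  if (d_ransac <= 0) stop("input error: d_ransac must be > 0")
  if (a_normals <= 0 || a_normals >= 180)
    stop("input error: a_normals must be in (0, 180)")
  structure(list(max_iter = as.integer(max_iter), d_ransac = d_ransac,
                 a_normals = a_normals, seed = as.integer(seed),
                 refit = isTRUE(refit), score = score),
            class = "ransac_params")
}

#' Normal-angle acceptance test
#'
#' Passes when for every pair the angle between the candidate-rotated moving
#' normal and the target normal is at most `a_normals` degrees. Pairs with a
#' zero normal are skipped with a warning.
#'
#' @param normals_m,normals_t n x 3 unit normals of the paired features.
#' @param transform candidate [rigid_transform()] (its rotation is applied
#'   to the moving normals).
#' @param a_normals threshold in degrees.
#' @return logical scalar.
#' @export
normal_test <- function(normals_m, normals_t, transform, a_normals = 60) {
  nm <- normals_m %*% t(transform$rotation)
  len_m <- sqrt(rowSums(nm^2))
  len_t <- sqrt(rowSums(normals_t^2))
  ok <- len_m > 1e-9 & len_t > 1e-9
  if (!all(ok)) warning(sum(!ok), " pairs with zero normals skipped")
  if (!any(ok)) return(TRUE)
  cosang <- rowSums(nm[ok, , drop = FALSE] * normals_t[ok, , drop = FALSE]) /
    (len_m[ok] * len_t[ok])
  all(acos(pmin(pmax(cosang, -1), 1)) <= a_normals * pi / 180 + 1e-12)
}

#' RANSAC rigid-transform estimation from pruned correspondences
#'
#' Random minimal (3-pair) subsets of the pruned correspondence set are
#' turned into candidate rigid transforms; each is scored by the RMSE of the
#' transformed moving features against the target features over the whole
#' set. A candidate is accepted as soon as its RMSE is below `d_ransac` and
#' the normal-angle test passes on every pair; if no candidate qualifies
#' within the iteration cap, the fallback flag is set and the best
#' consensus transform over all iterations is returned (most pairs within
#' `d_ransac`, smallest RMSE as tie-break -- which reduces to the plain
#' smallest-RMSE transform when no pair fits anywhere). With `refit = TRUE`
#' the returned
#' transform is re-estimated on the inlier pairs (residual < `d_ransac`) of
#' the selected model when at least 3 exist.
#'
#' @param src,dst n x 3 matched feature coordinates (moving, target), mm.
#' @param normals_m,normals_t n x 3 unit normals at those features.
#' @param params a [ransac_params()].
#' @return class `registration_result`: `transform`, `rmse` (mm), `inliers`
#'   (indices with residual < `d_ransac`), `accepted`, `fallback`,
#'   `residuals`.
#' @export
ransac_rigid <- function(src, dst, normals_m = NULL, normals_t = NULL,
                         params = ransac_params()) {
  src <- as_coord_matrix(src, "src")
  dst <- as_coord_matrix(dst, "dst")
  n <- nrow(src)
  if (n < 3L)
    stop("input error: fewer than 3 pruned correspondences; ",
         "relax the matching parameters (larger k or more features)")
  check_normals <- !is.null(normals_m) && !is.null(normals_t)
  set.seed(params$seed)
  best_rmse <- Inf
  best_count <- -1L
  best_tf <- NULL
  accepted <- FALSE
  for (it in seq_len(params$max_iter)) {
    pick <- sample.int(n, 3L)
    tf <- tryCatch(estimate_rigid(src[pick, ], dst[pick, ]),
                   error = function(e) NULL)
    if (is.null(tf)) next
    res <- residuals_rigid(tf, src, dst)
    rmse <- sqrt(mean(res^2))
    # consensus model selection: most pairs within d_ransac, smallest RMSE
    # as tie-break (with no inliers anywhere this is the plain smallest-RMSE
    # transform over all iterations); "rmse" mode ignores the count
    count <- if (params$score == "consensus") sum(res < params$d_ransac) else 0L
    if (count > best_count || (count == best_count && rmse < best_rmse)) {
      best_rmse <- rmse
      best_count <- count
      best_tf <- tf
    }
    if (rmse < params$d_ransac &&
        (!check_normals || normal_test(normals_m, normals_t, tf,
                                       params$a_normals))) {
      accepted <- TRUE
      best_tf <- tf
      best_rmse <- rmse
      break
    }
  }
  if (is.null(best_tf))
    stop("degenerate sample: no valid minimal subset found")
  fallback <- !accepted
  if (params$refit) {
    res <- residuals_rigid(best_tf, src, dst)
    inl <- which(res < params$d_ransac)
    if (length(inl) >= 3L) {
      tf2 <- tryCatch(estimate_rigid(src[inl, , drop = FALSE],
                                     dst[inl, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(tf2)) best_tf <- tf2
    }
  }
  res <- residuals_rigid(best_tf, src, dst)
  rmse <- sqrt(mean(res^2))
  normals_ok <- !check_normals ||
    normal_test(normals_m, normals_t, best_tf, params$a_normals)
  structure(list(transform = best_tf, rmse = rmse,
                 inliers = which(res < params$d_ransac),
                 residuals = res,
                 accepted = rmse < params$d_ransac && normals_ok,
                 fallback = fallback, seed = params$seed),
            class = "registration_result")
}

residuals_rigid <- function(tf, src, dst) {
  sqrt(rowSums((apply_transform(tf, src) - dst)^2))
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: RMSE %.3f mm, %d inliers, %s%s\n",
              x$rmse, length(x$inliers),
              if (x$accepted) "accepted" else "not accepted",
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' Point-to-point ICP refinement
#'
#' Alternates closest-point pairing with the closed-form rigid estimate,
#' starting from `init`, until the closest-point RMSE improves by less than
#' `tol`. Pairing runs from the target points into the transformed moving
#' surface: the intraoperative target is a partial view of the moving model,
#' so every target point has a valid counterpart while the converse is
#' false. The RMSE trace is non-increasing; the best iterate is returned
#' (with a warning if the iteration cap is hit before convergence).
#'
#' @param moving,target [surface_mesh()] or [point_cloud()] (or n x 3
#'   matrices).
#' @param init initial [rigid_transform()] (e.g. from [ransac_rigid()]).
#' @param max_iter iteration cap.
#' @param tol RMSE-change convergence tolerance (mm).
#' @return a [rigid_transform()] with attributes `rmse` and `trace`.
#' @export
refine_icp <- function(moving, target, init = rigid_transform(),
                       max_iter = 50L, tol = 1e-4) {
  src <- extract_points(moving)
  dstv <- extract_points(target)
  tf <- init
  trace <- numeric(0)
  best <- NULL
  best_rmse <- Inf
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(tf, src)
    nn <- as.integer(nn_index_cpp(dstv, moved))
    matched <- src[nn, , drop = FALSE]
    rmse <- sqrt(mean(rowSums((moved[nn, , drop = FALSE] - dstv)^2)))
    trace <- c(trace, rmse)
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- tf
    }
    if (it > 1 && trace[it - 1] - rmse < tol) break
    tf <- estimate_rigid(matched, dstv)
  }
  if (length(trace) == max_iter && trace[max_iter - 1] - trace[max_iter] >= tol)
    warning("ICP did not converge within ", max_iter, " iterations")
  attr(best, "rmse") <- best_rmse
  attr(best, "trace") <- trace
  best
}

extract_points <- function(x) {
  if (inherits(x, "surface_mesh")) x$vertices
  else if (inherits(x, "point_cloud")) x$points
  else as_coord_matrix(x, "points")
}

#' Ground-truth registration error
#'
#' Per-point distance between the transformed source positions and their
#' known ground-truth target positions (ground-truth vertex correspondences
#' on synthetic data, or marker positions: the target registration error).
#'
#' @param transform estimated [rigid_transform()].
#' @param src n x 3 source positions (mm).
#' @param dst n x 3 ground-truth target positions (mm).
#' @return list with `mean`, `sd`, `errors` (mm).
#' @export
evaluate_registration <- function(transform, src, dst) {
  src <- as_coord_matrix(src, "src")
  dst <- as_coord_matrix(dst, "dst")
  if (nrow(src) == 0L) stop("input error: empty ground truth")
  e <- sqrt(rowSums((apply_transform(transform, src) - dst)^2))
  list(mean = mean(e), sd = sd(e), errors = e)
}

#' Best-case rigid marker alignment (TRE)
#'
#' Rigidly aligns a set of marker positions measured before deformation to
#' the same markers after deformation and reports the residual target
#' registration error. This is the best any rigid registration can do on a
#' deforming organ.
#'
#' @param before,after n x 3 matched marker positions (mm).
#' @return list with `mean`, `sd`, `errors` (mm) and `transform`.
#' @export
marker_tre <- function(before, after) {
  tf <- estimate_rigid(before, after)
  out <- evaluate_registration(tf, before, after)
  out$transform <- tf
  out
}

#' Write a rigid transform (with quality metrics) as JSON and a 4x4 matrix
#'
#' @param result a `registration_result` or [rigid_transform()].
#' @param path output JSON path; a sibling `<path>.mat.txt` holds the 4x4
#'   row-major matrix.
#' @export
write_transform <- function(result, path) {
  tf <- if (inherits(result, "registration_result")) result$transform else result
  obj <- list(rotation = as.numeric(t(tf$rotation)),
              translation = tf$translation)
  if (inherits(result, "registration_result")) {
    obj$rmse_mm <- result$rmse
    obj$accepted <- result$accepted
    obj$fallback <- result$fallback
    obj$seed <- result$seed
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  utils::write.table(m, paste0(path, ".mat.txt"), row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
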