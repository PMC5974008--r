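CACHE_SCHEMA <- "contourreg-cache-1"

#' Precompute the moving-surface side of the registration
#'
#' Feature points, TOLDI descriptors and the feature-to-feature and
#' feature-to-contour geodesic tables of the preoperative mesh are computed
#' once (before surgery) so that registration against a new intraoperative
#' surface only has to process the target side.
#'
#' @param moving a [surface_mesh()] (role M).
#' @param contour ordered n x 3 ridge-line points on the moving surface.
#' @param config a [pipeline_config()].
#' @param mask optional visibility mask (vertex indices of the
#'   intraoperatively visible part of M).
#' @return class `moving_cache`.
#' @export
precompute_moving <- function(moving, contour, config = pipeline_config(),
                              mask = NULL) {
  stopifnot(inherits(moving, "surface_mesh"))
  cs <- contour_set(moving, contour)
  n <- min(config$n_features_moving,
           if (is.null(mask)) nrow(moving$vertices) else length(mask))
  feats <- if (config$sampling == "fps")
    farthest_point_sampling(moving, n, mask = mask,
                            seed = derive_seed(config$seed, 1L))
  else
    normal_space_sampling(moving, n, mask = mask,
                          seed = derive_seed(config$seed, 1L))
  desc <- compute_toldi(moving, feats, radius = config$toldi_radius,
                        L = config$toldi_L)
  dg <- geodesic_matrix(moving, feats$indices)
  structure(list(schema = CACHE_SCHEMA, mesh = moving, features = feats,
                 descriptors = desc, geodesics = dg,
                 contour = cs, b_dist = cs$field[feats$indices],
                 config = config),
            class = "moving_cache")
}

#' Save / load a precompute cache
#'
#' Single-archive serialisation of the moving-side precomputation, tagged
#' with a schema version; loading validates the tag.
#'
#' @param cache a `moving_cache`.
#' @param path archive path.
#' @export
save_cache <- function(cache, path) {
  stopifnot(inherits(cache, "moving_cache"))
  saveRDS(unclass(cache), path)
  invisible(path)
}

#' @rdname save_cache
#' @export
load_cache <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("schema error: cannot read cache archive: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, CACHE_SCHEMA))
    stop("schema error: not a ", CACHE_SCHEMA, " archive")
  structure(obj, class = "moving_cache")
}

#' Contour-constrained global surface registration
#'
#' The full alignment pipeline: reconstruct the target surface if it is a
#' point cloud, sample feature points, compute TOLDI descriptors, generate
#' descriptor k-NN candidate correspondences, prune them by spectral
#' matching on the contour-constrained affinity matrix, estimate the rigid
#' transform by RANSAC with RMSE and normal-angle acceptance, and optionally
#' refine with ICP. Requires no initial pose.
#'
#' @param moving a [surface_mesh()] or a `moving_cache` from
#'   [precompute_moving()].
#' @param target a [surface_mesh()] or [point_cloud()].
#' @param target_contour ordered n x 3 ridge-line points on the target (not
#'   needed for `algorithm = "R"` / `"SM+R1"`).
#' @param moving_contour ridge-line points on the moving surface; ignored
#'   when `moving` is a cache.
#' @param config a [pipeline_config()].
#' @param algorithm `"SM+R2"` (spectral matching with the geodesic and
#'   contour terms), `"SM+R1"` (geodesic term only, `alpha = 1`) or `"R"`
#'   (RANSAC directly on the unpruned candidate set).
#' @param mask optional visibility mask on the moving surface.
#' @return class `pipeline_result`: `transform`, `rmse`, `accepted`,
#'   `fallback`, `C`, `C_p`, `ransac`, `target` (the reconstructed surface
#'   when the input was a cloud), `config`, `algorithm`.
#' @export
register_surfaces <- function(moving, target, target_contour = NULL,
                              moving_contour = NULL,
                              config = pipeline_config(),
                              algorithm = c("SM+R2", "SM+R1", "R"),
                              mask = NULL) {
  algorithm <- match.arg(algorithm)
  need_contour <- algorithm == "SM+R2" && config$alpha < 1
  if (inherits(moving, "moving_cache")) {
    cache <- moving
  } else {
    if (need_contour && is.null(moving_contour))
      stop("missing contour: supply the moving-surface ridge line ",
           "(moving_contour) or a precompute cache")
    cfg_m <- config
    if (!need_contour && is.null(moving_contour)) {
      # contour unused by R / SM+R1: anchor the cache on a dummy vertex
      moving_contour <- moving$vertices[1, , drop = FALSE]
    }
    cache <- precompute_moving(moving, moving_contour, cfg_m, mask = mask)
  }
  if (need_contour && is.null(target_contour))
    stop("missing contour: supply the target-surface ridge line ",
         "(target_contour)")

  # --- target side ---
  if (inherits(target, "point_cloud"))
    target <- reconstruct_surface(target, k = config$recon_k)
  nt <- nrow(target$vertices)
  n_feat_t <- min(config$n_features, nt)
  feats_t <- if (config$sampling == "fps")
    farthest_point_sampling(target, n_feat_t,
                            seed = derive_seed(config$seed, 2L))
  else
    normal_space_sampling(target, n_feat_t,
                          seed = derive_seed(config$seed, 2L))
  radius <- if (is.null(config$toldi_radius))
    cache$descriptors$radius else config$toldi_radius
  desc_t <- compute_toldi(target, feats_t, radius = radius,
                          L = config$toldi_L)
  C <- candidate_correspondences(cache$descriptors, desc_t, k = config$k)

  if (algorithm == "R") {
    C_p <- C
    C_p$stage <- "C_p"
  } else {
    dg_t <- geodesic_matrix(target, feats_t$indices)
    b_m <- b_t <- NULL
    if (algorithm == "SM+R2" && config$alpha < 1) {
      cs_t <- contour_set(target, target_contour)
      b_m <- cache$b_dist
      b_t <- cs_t$field[feats_t$indices]
      # features unreachable from a contour (disconnected patch) cannot be
      # constrained: drop those candidates rather than failing
      drop <- !is.finite(b_m[C$pairs$m]) | !is.finite(b_t[C$pairs$t])
      if (any(drop)) C$pairs <- C$pairs[!drop, , drop = FALSE]
      if (nrow(C$pairs) == 0L)
        stop("input error: no candidates reachable from the contours")
    }
    params <- affinity_params(
      sigma_d = config$sigma_d, sigma_b = config$sigma_b,
      alpha = if (algorithm == "SM+R1") 1 else config$alpha,
      eps = config$eps)
    W <- build_affinity(C, cache$geodesics, dg_t, b_m, b_t, params)
    C_p <- spectral_prune(W, C, min_component = config$min_component,
                          max_pairs = config$max_pairs)
  }
  if (nrow(C_p$pairs) < 3L)
    stop("input error: fewer than 3 pruned correspondences; ",
         "relax the matching parameters")

  src <- cache$mesh$vertices[C_p$pairs$m_vertex, , drop = FALSE]
  dst <- target$vertices[C_p$pairs$t_vertex, , drop = FALSE]
  nm <- cache$mesh$normals[C_p$pairs$m_vertex, , drop = FALSE]
  ntn <- target$normals[C_p$pairs$t_vertex, , drop = FALSE]
  rp <- ransac_params(max_iter = config$ransac_iter,
                      d_ransac = config$d_ransac,
                      a_normals = config$a_normals,
                      seed = derive_seed(config$seed, 3L),
                      refit = config$refit, score = config$ransac_score)
  rr <- ransac_rigid(src, dst, nm, ntn, rp)
  tf <- rr$transform
  if (isTRUE(config$refine))
    tf <- refine_icp(cache$mesh, target, init = tf,
                     max_iter = config$icp_iter, tol = config$icp_tol)
  structure(list(transform = tf, rmse = rr$rmse, accepted = rr$accepted,
                 fallback = rr$fallback, C = C, C_p = C_p, ransac = rr,
                 target = target, config = config, algorithm = algorithm),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result [%s]: |C| = %d, |C_p| = %d, RMSE %.2f mm, %s%s\n",
    x$algorithm, nrow(x$C$pairs), nrow(x$C_p$pairs), x$rmse,
    if (x$accepted) "accepted" else "not accepted",
    if (x$fallback) " (fallback)" else ""))
  invisible(x)
}
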