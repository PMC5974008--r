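#' Pipeline configuration
#'
#' All tunable parameters of the precompute/register workflow with their
#' default operating point: `sigma_d = sigma_b = 0.3`, `alpha = 0.6`, 1000
#' RANSAC iterations, `a_normals = 60` degrees, `d_ransac = 10` mm (use 5 mm
#' for rigid-only scenarios). Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_features = 100L,       # feature points on the target surface
    n_features_moving = 1500L, # feature cap on the moving surface (dense:
                             # correct pairs then have near-zero residual,
                             # which the d_ransac acceptance presumes)
    k = 5L,                  # descriptor neighbours per target feature
    sampling = "fps",        # "fps" or "normal_space"
    toldi_radius = NULL,     # mm; NULL = 15% of the bounding-box diagonal
    toldi_L = 20L,           # depth-image width (descriptor length 3 L^2)
    sigma_d = 0.3,           # geodesic-consistency bandwidth
    sigma_b = 0.3,           # contour bandwidth
    alpha = 0.6,             # pairwise mixing weight
    eps = 1e-8,              # ratio guard (mm)
    min_component = 1e-3,    # spectral greedy relative threshold
    max_pairs = 20L,         # spectral greedy acceptance cap (|C_p|)
    ransac_iter = 1000L,
    d_ransac = 10,           # mm (5 in the rigid benchmark)
    a_normals = 60,          # degrees
    refit = TRUE,            # consensus refit of the RANSAC transform
    ransac_score = "consensus", # best-model rule: "consensus" or "rmse"
    refine = FALSE,          # run point-to-point ICP after RANSAC
    icp_iter = 50L,
    icp_tol = 1e-4,
    recon_k = 10L,           # reconstruction neighbourhood
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("config error: unknown parameter(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$n_features >= 1, cfg$n_features_moving >= 1, cfg$k >= 1,
            cfg$sampling %in% c("fps", "normal_space"),
            cfg$toldi_L >= 2, cfg$sigma_d > 0, cfg$sigma_b > 0,
            cfg$alpha >= 0, cfg$alpha <= 1, cfg$eps > 0,
            cfg$ransac_score %in% c("consensus", "rmse"),
            cfg$ransac_iter >= 1, cfg$d_ransac > 0,
            cfg$a_normals > 0, cfg$a_normals < 180)
  structure(cfg, class = "pipeline_config")
}

# per-stage seeds derived from the single top-level seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483587)
}
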