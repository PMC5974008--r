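#' Basic generated test meshes
#'
#' `icosphere()` subdivides an icosahedron and projects onto the unit sphere
#' (scaled by `radius`); `grid_mesh()` triangulates a regular planar grid at
#' z = 0. Both are used as analytic ground truth for the geodesic solver.
#'
#' @param subdiv subdivision level (0 = icosahedron, each level quadruples
#'   the triangle count).
#' @param radius sphere radius (mm).
#' @return a [surface_mesh()].
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_id <- new.env()
    nv <- nrow(v)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_id[[key]])) return(edge_id[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      nv <<- nv + 1L
      edge_id[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  surface_mesh(v * radius, f)
}

#' @param nx,ny grid points per side.
#' @param spacing grid spacing (mm).
#' @rdname icosphere
#' @export
grid_mesh <- function(nx = 11L, ny = 11L, spacing = 1) {
  v <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * spacing,
                             y = (seq_len(ny) - 1) * spacing, z = 0))
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  surface_mesh(v, f)
}

#' Synthetic liver-like mesh with a known ridge line
#'
#' A closed two-lobed organ shape at human-liver scale: a superellipsoid
#' (exponent `power`, half-extents `a`, `b`, `c` in mm) whose lower half is
#' compressed, producing a sharp anterior-inferior edge along the z = 0
#' equator (the "ridge line" of a real liver), and whose right lobe (x > 0)
#' is enlarged by a smooth taper. The ridge contour is the image of the
#' front (y < 0) half of the equator, returned as an ordered polyline.
#'
#' @param subdiv icosphere subdivision level controlling resolution.
#' @param a,b,c half-extents (mm).
#' @param power superellipsoid exponent (> 2 gives the boxy, sharp-edged
#'   shape).
#' @param contour_n number of points in the returned ridge polyline.
#' @return list with `mesh` (a [surface_mesh()], role M) and `contour`
#'   (`contour_n` x 3 ordered ridge points, mm).
#' @export
synthetic_liver <- function(subdiv = 3L, a = 100, b = 65, c = 40,
                            power = 3, contour_n = 120L) {
  sph <- icosphere(subdiv)
  # fixed surface-relief bumps (unit directions, amplitude, angular width):
  # they give the surface local texture, as vessels/ligament impressions do
  bump_dir <- rbind(c(0.8, 0.5, 0.6), c(-0.6, 0.5, 0.9), c(0.2, -0.8, 0.7),
                    c(-0.9, -0.4, 0.5), c(0.6, -0.3, -0.9), c(-0.3, 0.9, -0.4))
  bump_dir <- bump_dir / sqrt(rowSums(bump_dir^2))
  bump_amp <- c(0.10, -0.08, 0.09, -0.07, 0.08, 0.06)
  shape <- function(u) {
    s <- (abs(u[, 1] / a)^power + abs(u[, 2] / b)^power +
            abs(u[, 3] / c)^power)^(-1 / power)
    rad <- rep(1, nrow(u))
    for (k in seq_len(nrow(bump_dir))) {
      ang <- acos(pmin(pmax(as.numeric(u %*% bump_dir[k, ]), -1), 1))
      rad <- rad + bump_amp[k] * exp(-(ang / 0.45)^2)
    }
    p <- u * (s * rad)
    # sharp ridge: compress the lower half with a narrow sigmoid blend
    p[, 3] <- p[, 3] * (1 - 0.35 / (1 + exp(p[, 3] / 2)))
    # wedge taper: the left lobe (x < 0) is thin and narrow, the right lobe
    # bulky, breaking the left-right near-symmetry of the superellipsoid
    wedge <- 1 + 0.35 * tanh(p[, 1] / (0.45 * a))
    p[, 2] <- p[, 2] * wedge
    p[, 3] <- p[, 3] * wedge
    p[, 1] <- p[, 1] * (1 + 0.25 * tanh(p[, 1] / (0.5 * a)))
    p
  }
  mesh <- surface_mesh(shape(sph$vertices), sph$triangles, role = "M")
  t_par <- seq(pi, 2 * pi, length.out = contour_n)  # y < 0 half of the equator
  contour <- shape(cbind(cos(t_par), sin(t_par), 0))
  list(mesh = mesh, contour = contour)
}

#' Crop a geodesic-disk partial view
#'
#' Emulates the restricted laparoscopic view: a disk grown by geodesic
#' distance from a seed surface point until the cropped triangle area
#' reaches `fraction` of the original area (within 2%). The index map
#' retains original vertex ids for ground-truth scoring.
#'
#' @param mesh a [surface_mesh()].
#' @param fraction target area fraction in (0, 1].
#' @param seed RNG seed choosing the disk centre.
#' @param near optional vertex indices; the centre is drawn from them (used
#'   to keep the ridge line inside the view).
#' @return a [surface_mesh()] (role T) with attribute `index_map`: original
#'   vertex id of each cropped vertex.
#' @export
make_partial_view <- function(mesh, fraction, seed = 1L, near = NULL) {
  if (fraction <= 0 || fraction > 1)
    stop("input error: fraction must be in (0, 1]")
  nv <- nrow(mesh$vertices)
  if (fraction == 1) {
    out <- mesh
    out$role <- "T"
    attr(out, "index_map") <- seq_len(nv)
    return(out)
  }
  set.seed(seed)
  cand <- if (is.null(near)) seq_len(nv) else as.integer(near)
  centre <- cand[sample.int(length(cand), 1L)]
  d <- suppressWarnings(geodesic_distances(mesh, centre))$distances
  areas <- triangle_areas(mesh$vertices, mesh$triangles)
  total <- sum(areas)
  # face enters the disk when its farthest vertex does: sweep the radius
  face_d <- pmax(d[mesh$triangles[, 1]],
                 pmax(d[mesh$triangles[, 2]], d[mesh$triangles[, 3]]))
  ord <- order(face_d)
  cum <- cumsum(areas[ord]) / total
  nkeep <- which.min(abs(cum - fraction))
  if (abs(cum[nkeep] - fraction) > 0.02)
    warning(sprintf("crop area fraction %.3f differs from target %.3f",
                    cum[nkeep], fraction))
  keep_faces <- ord[seq_len(nkeep)]
  submesh(mesh, keep_faces)
}

submesh <- function(mesh, faces) {
  f <- mesh$triangles[faces, , drop = FALSE]
  verts <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[verts] <- seq_along(verts)
  out <- surface_mesh(mesh$vertices[verts, , drop = FALSE],
                      matrix(remap[f], ncol = 3), role = "T")
  attr(out, "index_map") <- verts
  out
}

#' Smooth synthetic deformation with linear morph levels
#'
#' A radial-basis (Gaussian) blend of control-point displacements deforms
#' the mesh; `make_deformation_sequence()` returns the linear vertex morph
#' between the original shape (level 0) and the fully deformed one (level
#' `max_level`). Topology is unchanged. `liver_lobe_deformation()` supplies
#' the default protocol: control points on the left lobe pushed up and
#' medially, a large deformation at the top level.
#'
#' @param mesh a [surface_mesh()].
#' @param control n x 3 control point positions (mm).
#' @param displacement n x 3 displacements (mm) at the controls.
#' @param width Gaussian kernel width (mm); default the median
#'   inter-control distance.
#' @return `deform_rbf()`: the deformed mesh; `make_deformation_sequence()`:
#'   list of `max_level + 1` meshes (level 0 = original).
#' @export
deform_rbf <- function(mesh, control, displacement, width = NULL) {
  control <- as_coord_matrix(control, "control")
  displacement <- as_coord_matrix(displacement, "displacement")
  if (is.null(width)) {
    dd <- as.matrix(dist(control))
    width <- median(dd[dd > 0])
    if (!is.finite(width) || width <= 0) width <- bbox_diagonal(mesh) / 4
  }
  v <- mesh$vertices
  for (k in seq_len(nrow(control))) {
    w <- exp(-rowSums(sweep(v, 2, control[k, ])^2) / (2 * width^2))
    v <- v + outer(w, displacement[k, ])
  }
  out <- mesh
  out$vertices <- v
  compute_normals(out)
}

#' @param deformed the fully deformed mesh (same topology as `mesh`).
#' @param max_level number of morph levels (>= 1).
#' @rdname deform_rbf
#' @export
make_deformation_sequence <- function(mesh, deformed, max_level = 17L) {
  if (max_level < 1L) stop("input error: max_level must be >= 1")
  if (nrow(deformed$vertices) != nrow(mesh$vertices))
    stop("input error: morph endpoints must share topology")
  if (has_self_intersection_proxy(deformed))
    warning("deformed mesh may self-intersect")
  lapply(0:max_level, function(l) {
    w <- l / max_level
    out <- mesh
    out$vertices <- (1 - w) * mesh$vertices + w * deformed$vertices
    if (l == 0L) out else compute_normals(out)
  })
}

# cheap proxy: any face whose area collapses or flips against its neighbours
has_self_intersection_proxy <- function(mesh) {
  any(triangle_areas(mesh$vertices, mesh$triangles) < 1e-9)
}

#' @param liver output of [synthetic_liver()].
#' @param magnitude peak control displacement (mm) at the top morph level.
#' @rdname deform_rbf
#' @export
liver_lobe_deformation <- function(liver, magnitude = 40) {
  v <- liver$mesh$vertices
  lobe <- which(v[, 1] < quantile(v[, 1], 0.2))
  set.seed(7L)
  ctrl <- v[lobe[seq(1, length(lobe), length.out = 6)], , drop = FALSE]
  dirs <- cbind(0.45, 0.25, 0.85)[rep(1, nrow(ctrl)), ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  disp <- dirs * magnitude * seq(0.6, 1, length.out = nrow(ctrl))
  deform_rbf(liver$mesh, ctrl, disp)
}

#' Random rigid transform applied about the mesh centroid
#'
#' Rotation axis uniform on the sphere, angle uniform in `[0, max_angle]`,
#' translation direction uniform with magnitude uniform in
#' `[0, max_translation]`.
#'
#' @param mesh a [surface_mesh()].
#' @param seed RNG seed.
#' @param max_angle radians (default pi: any orientation).
#' @param max_translation mm (default one bounding-box diagonal).
#' @return list with `mesh` (transformed) and `transform` (the ground
#'   truth [rigid_transform()] including the centroid offset).
#' @export
apply_random_rigid <- function(mesh, seed = 1L, max_angle = pi,
                               max_translation = NULL) {
  if (is.null(max_translation)) max_translation <- bbox_diagonal(mesh)
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_angle)
  R <- rotation_from_axis_angle(ax, ang)
  tdir <- rnorm(3)
  tdir <- tdir / sqrt(sum(tdir^2))
  tr <- tdir * runif(1, 0, max_translation)
  ctr <- colMeans(mesh$vertices)
  tf <- rigid_transform(R, as.numeric(ctr - R %*% ctr) + tr)
  list(mesh = apply_transform(tf, mesh), transform = tf)
}

rotation_from_axis_angle <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Gaussian surface noise along vertex normals
#'
#' @param mesh a [surface_mesh()].
#' @param sigma displacement standard deviation (mm).
#' @param seed RNG seed.
#' @return the noisy mesh (normals recomputed).
#' @export
add_surface_noise <- function(mesh, sigma, seed = 1L) {
  if (sigma < 0) stop("input error: sigma must be >= 0")
  if (sigma == 0) return(mesh)
  set.seed(seed)
  mesh$vertices <- mesh$vertices +
    mesh$normals * rnorm(nrow(mesh$vertices), 0, sigma)
  compute_normals(mesh)
}

#' Robustness experiment over partial sizes and deformation levels
#'
#' Reproduces the synthetic protocol: the moving model is registered
#' against randomly posed partial views of itself (optionally deformed),
#' with each of the three algorithms, `runs` times per grid cell. Reported
#' error is the mean over the view's vertices of the distance between the
#' estimated-transform position and the ground-truth position.
#'
#' @param liver output of [synthetic_liver()] (or a compatible list with
#'   `mesh` and `contour`).
#' @param fractions partial-view area fractions.
#' @param levels deformation levels (0 = rigid), out of `max_level`.
#' @param algorithms subset of `c("R", "SM+R1", "SM+R2")`.
#' @param runs runs per (algorithm, fraction, level) cell.
#' @param seed top-level seed; every run's randomness derives from it.
#' @param config a [pipeline_config()]; `NULL` selects the benchmark
#'   operating point (`d_ransac = 5` mm for the rigid protocol, depth-image
#'   width 8, 150 target features, support radius 6% of the bounding-box
#'   diagonal -- small enough that a 7% partial view does not truncate most
#'   feature supports).
#' @param max_level top of the deformation scale.
#' @param noise_sigma surface noise (mm) added to each view, default 0.
#' @return data.frame: algorithm, fraction, level, run, mean_error_mm,
#'   accepted, fallback, failed.
#' @export
run_robustness_experiment <- function(liver,
                                      fractions = 0.23, levels = 0L,
                                      algorithms = c("R", "SM+R1", "SM+R2"),
                                      runs = 50L, seed = 1L,
                                      config = NULL,
                                      max_level = 17L,
                                      noise_sigma = 0) {
  stopifnot(runs >= 1L, all(levels <= max_level))
  mesh <- liver$mesh
  if (is.null(config))
    config <- pipeline_config(d_ransac = 5, toldi_L = 8L, n_features = 150L,
                              toldi_radius = 0.06 * bbox_diagonal(mesh),
                              ransac_score = "rmse")
  cache <- precompute_moving(mesh, liver$contour, config)
  seq_meshes <- NULL
  if (any(levels > 0L)) {
    deformed <- liver_lobe_deformation(liver)
    seq_meshes <- make_deformation_sequence(mesh, deformed, max_level)
  }
  contour_v <- contour_set(mesh, liver$contour)$vertices
  # crop centres near the ridge so every view contains contour points
  ridge_field <- geodesic_to_set(mesh, contour_v)
  near_ridge <- which(ridge_field < 0.18 * bbox_diagonal(mesh))

  grid <- expand.grid(fraction = fractions, level = levels, run = seq_len(runs))
  rows <- vector("list", nrow(grid) * length(algorithms))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    fr <- grid$fraction[g]
    lv <- grid$level[g]
    rn <- grid$run[g]
    rs <- derive_seed(seed, g)
    view <- make_partial_view(mesh, fr, seed = rs, near = near_ridge)
    imap <- attr(view, "index_map")
    src_mesh <- if (lv > 0L) seq_meshes[[lv + 1L]] else mesh
    tmesh <- view
    tmesh$vertices <- src_mesh$vertices[imap, , drop = FALSE]
    tmesh <- compute_normals(tmesh)
    if (noise_sigma > 0)
      tmesh <- add_surface_noise(tmesh, noise_sigma, seed = rs + 1L)
    rr <- apply_random_rigid(tmesh, seed = rs + 2L)
    tmesh <- rr$mesh
    gt_pos <- apply_transform(rr$transform,
                              src_mesh$vertices[imap, , drop = FALSE])
    # target contour: ridge points whose snapped vertex fell inside the view
    cvis <- contour_v[contour_v %in% imap]
    t_contour <- if (length(cvis))
      apply_transform(rr$transform, src_mesh$vertices[cvis, , drop = FALSE])
    else NULL
    for (alg in algorithms) {
      ri <- ri + 1L
      cfg <- config
      cfg$seed <- rs + 3L
      res <- tryCatch({
        pr <- register_surfaces(cache, tmesh, target_contour = t_contour,
                                config = cfg, algorithm = alg)
        ev <- evaluate_registration(pr$transform,
                                    mesh$vertices[imap, , drop = FALSE],
                                    gt_pos)
        data.frame(algorithm = alg, fraction = fr, level = lv, run = rn,
                   mean_error_mm = ev$mean, accepted = pr$accepted,
                   fallback = pr$fallback, failed = FALSE)
      }, error = function(e) {
        data.frame(algorithm = alg, fraction = fr, level = lv, run = rn,
                   mean_error_mm = NA_real_, accepted = FALSE,
                   fallback = TRUE, failed = TRUE)
      })
      rows[[ri]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise and plot robustness results
#'
#' `summarise_robustness()` aggregates mean and standard deviation of the
#' per-run errors per cell; `plot_robustness()` draws the error curves
#' (mean +/- sd against fraction or level, one line per algorithm; requires
#' ggplot2).
#'
#' @param results data.frame from [run_robustness_experiment()].
#' @return a data.frame / a ggplot object.
#' @export
summarise_robustness <- function(results) {
  ok <- results[!results$failed & is.finite(results$mean_error_mm), ]
  agg <- aggregate(mean_error_mm ~ algorithm + fraction + level, data = ok,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(agg[, 1:3],
                    mean_mm = agg$mean_error_mm[, "mean"],
                    sd_mm = agg$mean_error_mm[, "sd"],
                    n = agg$mean_error_mm[, "n"])
  out[order(out$algorithm, out$fraction, out$level), ]
}

#' @param by `"fraction"` or `"level"` for the x-axis.
#' @rdname summarise_robustness
#' @export
plot_robustness <- function(results, by = c("fraction", "level")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_robustness requires ggplot2")
  by <- match.arg(by)
  s <- summarise_robustness(results)
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[by]], y = .data$mean_mm,
                                  colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_mm - .data$sd_mm,
                                          ymax = .data$mean_mm + .data$sd_mm)) +
    ggplot2::labs(x = by, y = "mean ground-truth error (mm)") +
    ggplot2::theme_minimal()
}
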