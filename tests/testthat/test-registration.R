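test_that("rigid transforms validate, compose and invert exactly", {
  R0 <- rand_rotation(1)
  tf <- rigid_transform(R0, c(1, -2, 3))
  expect_error(rigid_transform(R0 * 1.1, c(0, 0, 0)), "orthonormal")
  pts <- matrix(rnorm(30), 10, 3)
  back <- apply_transform(invert_transform(tf), apply_transform(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-12)
  tf2 <- rigid_transform(rand_rotation(2), c(0, 5, 0))
  comp <- compose_transforms(tf2, tf)
  expect_equal(apply_transform(comp, pts),
               apply_transform(tf2, apply_transform(tf, pts)),
               tolerance = 1e-12)
})

test_that("least-squares rigid estimation recovers planted transforms", {
  set.seed(11)
  src <- matrix(rnorm(45, sd = 30), 15, 3)
  expect_equal(estimate_rigid(src, src)$rotation, diag(3), tolerance = 1e-12)
  expect_equal(estimate_rigid(src, src)$translation, c(0, 0, 0),
               tolerance = 1e-12)
  for (seed in 1:5) {
    R0 <- rand_rotation(seed)
    t0 <- rnorm(3, sd = 50)
    dst <- src %*% t(R0) + matrix(t0, 15, 3, byrow = TRUE)
    est <- estimate_rigid(src, dst)
    res <- apply_transform(est, src) - dst
    expect_lt(sqrt(max(rowSums(res^2))), 1e-9)
  }
  expect_error(estimate_rigid(src[1:2, ], src[1:2, ]), "3 point pairs")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimate_rigid(coll, coll), "collinear")
})

test_that("rigid estimation agrees with an exhaustive planar rotation search", {
  # 4-point planar toys: best rotation about z found by 1-degree grid scan
  set.seed(21)
  for (rep in 1:3) {
    src <- cbind(rnorm(4, sd = 10), rnorm(4, sd = 10), 0)
    ang0 <- runif(1, 0, 2 * pi)
    Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    dst <- src %*% t(Rz(ang0))
    dst <- dst + matrix(rnorm(12, sd = 0.05), 4, 3)  # slight noise
    grid_err <- vapply(seq(0, 359) * pi / 180, function(a)
      sum((src %*% t(Rz(a)) - sweep(dst, 2, colMeans(dst) -
        as.numeric(Rz(a) %*% colMeans(src))))^2), numeric(1))
    best_grid <- (which.min(grid_err) - 1) * pi / 180
    est <- estimate_rigid(src, dst)
    ang_est <- atan2(est$rotation[2, 1], est$rotation[1, 1]) %% (2 * pi)
    diff <- abs(ang_est - best_grid)
    expect_lt(min(diff, 2 * pi - diff), 1.01 * pi / 180)
  }
})

test_that("the normal test thresholds the rotated-normal angle", {
  n0 <- matrix(c(0, 0, 1), 1, 3)
  id <- rigid_transform()
  expect_true(normal_test(n0, n0, id, a_normals = 1e-6))
  n90 <- matrix(c(1, 0, 0), 1, 3)
  expect_false(normal_test(n0, n90, id, a_normals = 60))
  rot <- function(a) matrix(c(sin(a), 0, cos(a)), 1, 3)
  expect_true(normal_test(n0, rot(59.9 * pi / 180), id, a_normals = 60))
  expect_false(normal_test(n0, rot(60.1 * pi / 180), id, a_normals = 60))
  # the moving normal is rotated by the candidate transform before comparing
  Rz90 <- rigid_transform(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  nx <- matrix(c(1, 0, 0), 1, 3)
  ny <- matrix(c(0, 1, 0), 1, 3)
  expect_true(normal_test(nx, ny, Rz90, a_normals = 1))
  expect_warning(ok <- normal_test(matrix(0, 1, 3), n0, id), "zero normals")
  expect_true(ok)
})

test_that("RANSAC recovers planted transforms through gross outliers", {
  set.seed(31)
  src <- matrix(rnorm(30, sd = 40), 10, 3)
  nrm <- src / sqrt(rowSums(src^2))

  # clean case: accepted with essentially zero RMSE
  R0 <- rand_rotation(3)
  t0 <- c(10, -5, 20)
  dst <- src %*% t(R0) + matrix(t0, 10, 3, byrow = TRUE)
  res <- ransac_rigid(src, dst, nrm, nrm %*% t(R0),
                      ransac_params(d_ransac = 5, seed = 1))
  expect_true(res$accepted)
  expect_false(res$fallback)
  expect_lt(res$rmse, 1e-9)

  # 10 correct pairs + 3 gross (50 mm) outliers, 20 seeds
  for (seed in 1:20) {
    set.seed(seed + 100)
    out_idx <- sample.int(10, 3)
    dst_noisy <- dst
    off <- matrix(rnorm(9), 3, 3)
    dst_noisy[out_idx, ] <- dst_noisy[out_idx, ] +
      50 * off / sqrt(rowSums(off^2))
    r <- ransac_rigid(src, dst_noisy, params = ransac_params(d_ransac = 5,
                                                             seed = seed))
    ang <- acos(pmin(pmax((sum(diag(t(R0) %*% r$transform$rotation)) - 1) / 2,
                          -1), 1)) * 180 / pi
    expect_lt(ang, 1)
    expect_lt(sqrt(sum((r$transform$translation - t0)^2)), 1)
  }

  expect_error(ransac_rigid(src[1:2, ], dst[1:2, ]), "fewer than 3")
})

test_that("RANSAC falls back to the smallest-RMSE transform when nothing fits", {
  set.seed(41)
  src <- matrix(rnorm(24, sd = 30), 8, 3)
  dst <- matrix(rnorm(24, sd = 30), 8, 3)  # unrelated: nothing under threshold
  r <- ransac_rigid(src, dst, params = ransac_params(d_ransac = 1e-6,
                                                     seed = 5, refit = FALSE))
  expect_true(r$fallback)
  expect_false(r$accepted)
  # the returned transform is the argmin-RMSE minimal-sample solution:
  # replaying the same seeded sampling reproduces it
  set.seed(contourreg:::derive_seed(5, 0))  # not the internal stream: replay manually
  rp <- ransac_params(d_ransac = 1e-6, seed = 5, refit = FALSE)
  set.seed(rp$seed)
  best <- Inf
  best_tf <- NULL
  for (it in seq_len(rp$max_iter)) {
    pick <- sample.int(8, 3)
    tf <- tryCatch(estimate_rigid(src[pick, ], dst[pick, ]),
                   error = function(e) NULL)
    if (is.null(tf)) next
    rmse <- sqrt(mean(rowSums((apply_transform(tf, src) - dst)^2)))
    if (rmse < best) { best <- rmse; best_tf <- tf }
  }
  expect_equal(r$transform$rotation, best_tf$rotation, tolerance = 1e-12)
  expect_equal(r$rmse, best, tolerance = 1e-12)
})

test_that("RANSAC success rises with the inlier fraction", {
  set.seed(51)
  n <- 20
  src <- matrix(rnorm(3 * n, sd = 40), n, 3)
  R0 <- rand_rotation(7)
  t0 <- c(5, 5, -10)
  dst0 <- src %*% t(R0) + matrix(t0, n, 3, byrow = TRUE)
  success_rate <- function(inlier_frac) {
    ok <- 0
    for (seed in 1:50) {
      set.seed(seed)
      n_out <- round((1 - inlier_frac) * n)
      dst <- dst0
      idx <- sample.int(n, n_out)
      dst[idx, ] <- dst[idx, ] + matrix(rnorm(3 * n_out, sd = 60), n_out, 3)
      r <- ransac_rigid(src, dst,
                        params = ransac_params(d_ransac = 5, max_iter = 30,
                                               seed = seed))
      ang <- acos(pmin(pmax((sum(diag(t(R0) %*% r$transform$rotation)) - 1) / 2,
                            -1), 1)) * 180 / pi
      ok <- ok + (ang < 2)
    }
    ok / 50
  }
  rates <- vapply(c(0.4, 0.6, 0.8), success_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("ICP refinement converges monotonically to sub-edge accuracy", {
  liver <- liver_fixture()
  m <- liver$mesh
  # already aligned: returns ~ the initial transform
  tf <- refine_icp(m, m, rigid_transform(), max_iter = 10, tol = 1e-6)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(attr(tf, "rmse"), 1e-12)

  # 5 mm / 5 degree perturbation of a rigid case
  pert <- rigid_transform(
    contourreg:::rotation_from_axis_angle(c(0, 0, 1), 5 * pi / 180),
    c(5, 0, 0))
  target <- apply_transform(invert_transform(pert), m)
  tf2 <- refine_icp(m, target, rigid_transform(), max_iter = 60, tol = 1e-8)
  moved <- apply_transform(tf2, m$vertices)
  nn <- contourreg:::nn_index_cpp(moved, target$vertices)
  expect_lt(mean(sqrt(rowSums((moved - target$vertices[nn, ])^2))), 0.5)
  expect_true(all(diff(attr(tf2, "trace")) <= 1e-9))
})

test_that("registration metrics match a brute-force distance computation", {
  expect_error(evaluate_registration(rigid_transform(),
                                     matrix(0, 0, 3), matrix(0, 0, 3)),
               "empty")
  pts <- matrix(rnorm(30, sd = 20), 10, 3)
  ev0 <- evaluate_registration(rigid_transform(), pts, pts)
  expect_identical(ev0$mean, 0)
  shift <- rigid_transform(diag(3), c(5, 0, 0))
  expect_equal(evaluate_registration(shift, pts, pts)$mean, 5)
  tf <- rigid_transform(rand_rotation(4), c(1, 2, 3))
  dst <- matrix(rnorm(30, sd = 20), 10, 3)
  ev <- evaluate_registration(tf, pts, dst)
  manual <- sqrt(rowSums((pts %*% t(tf$rotation) +
    matrix(tf$translation, 10, 3, byrow = TRUE) - dst)^2))
  expect_equal(ev$errors, manual, tolerance = 1e-12)
  expect_equal(ev$mean, mean(manual))
})

test_that("marker alignment reports the residual deformation as TRE", {
  set.seed(61)
  before <- matrix(rnorm(45, sd = 50), 15, 3)
  R0 <- rand_rotation(9)
  after <- before %*% t(R0) + matrix(c(3, 4, 5), 15, 3, byrow = TRUE)
  expect_lt(marker_tre(before, after)$mean, 1e-9)
  # superimposed non-rigid noise leaves a residual of that order
  after2 <- after + matrix(rnorm(45, sd = 2), 15, 3)
  tre <- marker_tre(before, after2)$mean
  expect_gt(tre, 0.5)
  expect_lt(tre, 6)
})

test_that("transforms serialise to JSON with quality metrics", {
  set.seed(71)
  src <- matrix(rnorm(30, sd = 30), 10, 3)
  R0 <- rand_rotation(5)
  dst <- src %*% t(R0) + 4
  r <- ransac_rigid(src, dst, params = ransac_params(d_ransac = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  write_transform(r, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(matrix(obj$rotation, 3, 3, byrow = TRUE), r$transform$rotation,
               tolerance = 1e-12)
  expect_true(obj$accepted)
  m <- as.matrix(read.table(paste0(path, ".mat.txt")))
  expect_equal(unname(m[1:3, 4]), r$transform$translation, tolerance = 1e-10)
})
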