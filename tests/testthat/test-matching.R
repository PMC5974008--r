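test_that("geodesic consistency ratio behaves as specified", {
  expect_lte(abs(geodesic_consistency(10, 10) - 1), 1.01 * 1e-8 / 10)
  expect_equal(geodesic_consistency(10, 20, eps = 1e-8), 0.5, tolerance = 1e-8)
  expect_lt(geodesic_consistency(10, 0), 1e-8)
  expect_equal(geodesic_consistency(7, 13), geodesic_consistency(13, 7))
  expect_error(geodesic_consistency(-1, 5), "negative")
  expect_error(geodesic_consistency(1, 5, eps = 0), "eps")

  # scale invariance: multiplying all distances by s changes c by < 1e-6
  set.seed(1)
  d1 <- runif(100, 1, 200)
  d2 <- runif(100, 1, 200)
  for (s in c(0.1, 3, 50))
    expect_lt(max(abs(geodesic_consistency(s * d1, s * d2) -
                      geodesic_consistency(d1, d2))), 1e-6)
})

test_that("rigidity kernel is a Gaussian in the consistency deficit", {
  expect_identical(rigidity_kernel(1, 0.3), 1)
  expect_equal(rigidity_kernel(0.7, 0.3), exp(-0.5), tolerance = 1e-12)
  expect_equal(rigidity_kernel(0.4, 0.3), exp(-2), tolerance = 1e-12)
  expect_error(rigidity_kernel(0.5, 0), "sigma")
  cs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(rigidity_kernel(cs, 0.3)) > 0))
})

test_that("contour term averages the two per-pair kernels symmetrically", {
  expect_equal(contour_term(5, 5, 12, 12, sigma_b = 0.3), 1, tolerance = 1e-7)
  # pair i consistent, pair j with ratio 0.7
  g2 <- contour_term(10, 10, 7, 10, sigma_b = 0.3)
  expect_equal(g2, (1 + exp(-0.5)) / 2, tolerance = 1e-6)
  expect_equal(contour_term(3, 8, 7, 10), contour_term(7, 10, 3, 8))
})

test_that("descriptor similarity is Gaussian with the median bandwidth", {
  expect_identical(descriptor_similarity(0, sigma_f = 1), 1)
  d <- c(0, 1, 2, 3, 4)
  s <- descriptor_similarity(d)  # sigma_f = median = 2
  expect_equal(s[3], exp(-0.5), tolerance = 1e-12)
  expect_true(all(diff(s) < 0))
  expect_error(descriptor_similarity(-1), "negative")
  # all-zero distances: bandwidth floored, no NaN
  expect_equal(descriptor_similarity(c(0, 0, 0)), rep(1, 3))
})

test_that("the affinity matrix mixes terms and zeroes conflicts", {
  # controlled 3-candidate instance with hand-computed entries
  C <- make_pairs(m = c(1, 2, 3), t = c(1, 2, 3), dist = c(0, 0, 0))
  dg_m <- dg_t <- matrix(c(0, 10, 20, 10, 0, 30, 20, 30, 0), 3, 3)
  # contour distances chosen so the inner kernel of candidate 2 is exp(-0.5)
  b_m <- c(10, 7, 5)
  b_t <- c(10, 10, 5)
  W <- build_affinity(C, dg_m, dg_t, b_m, b_t,
                      affinity_params(alpha = 0.6))
  # perfect geodesic consistency (g = 1); g_b(1,3) = 1 -> entry 0.6 + 0.4
  expect_equal(W[1, 3], 1, tolerance = 1e-6)
  # g_b(1,2) = (1 + exp(-0.5))/2
  expect_equal(W[1, 2], 0.6 + 0.4 * (1 + exp(-0.5)) / 2, tolerance = 1e-6)
  expect_identical(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(diag(W), rep(1, 3))  # zero descriptor distances

  # direct mixing example: g = 1, g_b ~= 0.5 -> 0.6 * 1 + 0.4 * 0.5 = 0.8
  # (g_b = 0.5 up to the tail mass of the inner Gaussian, < 0.4%)
  b_m2 <- c(10, 1e-9, 5)
  gb_half <- (1 + rigidity_kernel(geodesic_consistency(1e-9, 10), 0.3)) / 2
  expect_equal(gb_half, 0.5, tolerance = 0.01)
  W2 <- build_affinity(C, dg_m, dg_t, b_m2, b_t, affinity_params(alpha = 0.6))
  expect_equal(W2[1, 2], 0.8, tolerance = 0.01)
  expect_equal(W2[1, 2], 0.6 + 0.4 * gb_half, tolerance = 1e-9)

  # alpha = 1 drops the contour term entirely
  W3 <- build_affinity(C, dg_m, dg_t, params = affinity_params(alpha = 1))
  cons <- geodesic_consistency(dg_m, dg_t)
  expect_equal(W3[1, 2], rigidity_kernel(cons[1, 2], 0.3))

  # conflicting assignments are zeroed
  C4 <- make_pairs(m = c(1, 1, 2), t = c(1, 2, 2))
  W4 <- build_affinity(C4, dg_m, dg_t, params = affinity_params(alpha = 1))
  expect_identical(W4[1, 2], 0)  # shared m
  expect_identical(W4[2, 3], 0)  # shared t
  expect_gt(W4[1, 3], 0)

  # non-finite geodesics (disconnected) carry no support
  dg_inf <- dg_m
  dg_inf[1, 3] <- dg_inf[3, 1] <- Inf
  W5 <- build_affinity(C, dg_inf, dg_t, params = affinity_params(alpha = 1))
  expect_identical(W5[1, 3], 0)
})

test_that("spectral pruning matches exhaustive maximisation on planted instances", {
  for (case in list(c(4, 3), c(5, 3), c(4, 4), c(6, 2), c(3, 5))) {
    for (seed in 1:4) {
      inst <- planted_instance(case[1], case[2], seed)
      got <- sort(spectral_prune(inst$W, inst$C)$pairs$m)
      want <- sort(inst$C$pairs$m[brute_force_prune(inst$W, inst$C$pairs)])
      expect_identical(got, want)
      expect_identical(got, seq_len(case[1]))  # exactly the planted cluster
    }
  }
})

test_that("spectral pruning handles diagonal and degenerate affinities", {
  C <- make_pairs(1:4, 1:4)
  W <- diag(c(0.2, 0.9, 0.5, 0.1))
  got <- spectral_prune(W, C)
  expect_identical(got$pairs$m, 2L)  # single candidate with the largest unary
  expect_identical(got$stage, "C_p")

  expect_warning(empty <- spectral_prune(matrix(0, 4, 4), C), "all-zero")
  expect_identical(nrow(empty$pairs), 0L)

  # one-to-one in both feature sets
  set.seed(5)
  Cbig <- make_pairs(m = sample(1:6, 12, TRUE), t = rep(1:6, 2))
  Wb <- matrix(runif(144, 0.4, 1), 12, 12)
  Wb <- (Wb + t(Wb)) / 2
  pruned <- spectral_prune(Wb, Cbig)$pairs
  expect_false(anyDuplicated(pruned$m) > 0)
  expect_false(anyDuplicated(pruned$t) > 0)
})

test_that("contours snap to the surface and reject distant polylines", {
  liver <- liver_fixture()
  cs <- contour_set(liver$mesh, liver$contour)
  expect_true(all(cs$field[cs$vertices] == 0))
  expect_true(all(cs$field >= 0))
  far <- liver$contour + 300
  expect_error(contour_set(liver$mesh, far), "mm from the surface")
})

test_that("pruning enriches correct pairs on a rigid synthetic case", {
  liver <- liver_fixture4()
  mesh <- liver$mesh
  cfg <- bench_config(mesh)
  cache <- precompute_moving(mesh, liver$contour, cfg)
  cs <- contour_set(mesh, liver$contour)
  near <- which(geodesic_to_set(mesh, cs$vertices) < 0.18 * bbox_diagonal(mesh))
  view <- make_partial_view(mesh, 0.23, seed = 31, near = near)
  imap <- attr(view, "index_map")
  rigid <- apply_random_rigid(compute_normals(view), seed = 32)
  cvis <- cs$vertices[cs$vertices %in% imap]
  tc <- apply_transform(rigid$transform, mesh$vertices[cvis, , drop = FALSE])
  pr <- register_surfaces(cache, rigid$mesh, target_contour = tc,
                          config = cfg, algorithm = "SM+R2")
  edge <- mean_edge_length(mesh)
  frac_good <- function(p)
    mean(sqrt(rowSums((mesh$vertices[p$m_vertex, , drop = FALSE] -
                       mesh$vertices[imap[p$t_vertex], , drop = FALSE])^2)) < edge)
  expect_gt(frac_good(pr$C_p$pairs), frac_good(pr$C$pairs))
})

test_that("the QAP energy decreases from the candidate set to the pruned set", {
  # diagnostic energy: pruned one-to-one subsets of consistent pairs score
  # lower per-pair energy than the raw candidate set
  C <- make_pairs(m = c(1, 2, 3, 1, 2), t = c(1, 2, 3, 2, 1),
                  dist = c(0.1, 0.1, 0.1, 0.9, 0.9))
  dg_m <- matrix(c(0, 10, 20, 10, 0, 15, 20, 15, 0), 3, 3)
  dg_t <- dg_m
  Cp <- C
  Cp$pairs <- C$pairs[1:3, ]
  e_all <- qap_energy(C, dg_m, dg_t) / 5
  e_p <- qap_energy(Cp, dg_m, dg_t) / 3
  expect_lt(e_p, e_all)
})
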