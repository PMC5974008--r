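test_that("mesh I/O round-trips across formats and rejects malformed input", {
  cube <- cube_mesh()
  expect_equal(nrow(cube$vertices), 8L)
  expect_equal(nrow(cube$triangles), 12L)

  for (spec in list(list(ext = "ply", binary = FALSE),
                    list(ext = "ply", binary = TRUE),
                    list(ext = "obj", binary = FALSE),
                    list(ext = "stl", binary = FALSE),
                    list(ext = "stl", binary = TRUE))) {
    path <- tempfile(fileext = paste0(".", spec$ext))
    write_surface(cube, path, binary = spec$binary)
    back <- load_surface(path)
    if (spec$ext == "stl") {
      # STL stores triangle soup: compare vertex sets and triangle count
      expect_equal(nrow(back$triangles), nrow(cube$triangles))
      expect_equal(dim(back$vertices), dim(cube$vertices))
      reord <- contourreg:::nn_index_cpp(back$vertices, cube$vertices)
      expect_equal(back$vertices, cube$vertices[reord, ], tolerance = 1e-6)
    } else {
      expect_equal(back$vertices, cube$vertices)
      expect_equal(back$triangles, cube$triangles)
    }
    unlink(path)
  }

  # point-cloud PLY (no faces) and CSV
  cl <- point_cloud(matrix(rnorm(300), 100, 3))
  p1 <- tempfile(fileext = ".ply")
  write_surface(cl, p1)
  expect_s3_class(load_surface(p1), "point_cloud")
  p2 <- tempfile(fileext = ".csv")
  write_surface(cl, p2)
  expect_equal(load_surface(p2)$points, cl$points, tolerance = 1e-12)

  # truncated PLY
  bad <- tempfile(fileext = ".ply")
  full <- tempfile(fileext = ".ply")
  write_surface(cube, full)
  lines <- readLines(full)
  writeLines(lines[1:(length(lines) - 6)], bad)
  expect_error(load_surface(bad), "truncated|parse")
  expect_error(load_surface(tempfile(fileext = ".ply")), "not found")
})

test_that("vertex normals are unit length, planar-exact and sphere-accurate", {
  g <- grid_mesh(11, 11, 1)
  expect_true(all(abs(abs(g$normals[, 3]) - 1) < 1e-12))

  s <- icosphere(3)
  len <- sqrt(rowSums(s$normals^2))
  expect_true(all(abs(len - 1) < 1e-6))
  dirs <- s$vertices / sqrt(rowSums(s$vertices^2))
  expect_true(all(rowSums(s$normals * dirs) > 0.99))
})

test_that("closed meshes are oriented outward regardless of input winding", {
  cube <- cube_mesh()
  flipped <- surface_mesh(cube$vertices, cube$triangles[, c(1, 3, 2)])
  expect_gt(contourreg:::signed_volume(flipped$vertices, flipped$triangles), 0)
})

test_that("fast-marching geodesics match planar and spherical ground truth", {
  g <- grid_mesh(21, 21, 1)
  gf <- geodesic_distances(g, 1L)
  expect_identical(gf$distances[1], 0)
  # 10 mm along an axis and along the diagonal, both within 2%
  expect_lt(abs(gf$distances[11] - 10) / 10, 0.02)
  expect_lt(abs(gf$distances[21 * 10 + 11] - sqrt(200)) / sqrt(200), 0.02)

  s <- icosphere(4)
  ds <- geodesic_distances(s, 1L)$distances
  antipode <- which.min(rowSums(sweep(s$vertices, 2, -s$vertices[1, ])^2))
  expect_lt(abs(ds[antipode] - pi) / pi, 0.03)

  expect_error(geodesic_distances(g, integer(0)), "no source")
  expect_error(geodesic_distances(g, 10000L), "out of range")
})

test_that("disconnected components are reported as unreachable", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(10, 10, 0), c(11, 10, 0), c(10, 11, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_warning(gf <- geodesic_distances(m, 1L), "unreachable")
  expect_true(all(is.infinite(gf$distances[4:6])))
  expect_true(all(is.finite(gf$distances[1:3])))
})

test_that("geodesics dominate Euclidean distance and respect Dijkstra bounds", {
  skip_if_not_installed("igraph")
  liver <- liver_fixture()
  m <- liver$mesh
  for (src in c(1L, 200L)) {
    fmm <- suppressWarnings(geodesic_distances(m, src))$distances
    eu <- sqrt(rowSums(sweep(m$vertices, 2, m$vertices[src, ])^2))
    expect_true(all(fmm >= eu * 0.99))
    dij <- dijkstra_oracle(m, src)
    # Dijkstra on the edge graph overestimates; fast marching must never
    # exceed it
    expect_true(all(fmm <= dij * (1 + 1e-9)))
  }
  # on the near-equilateral icosphere the edge-graph distortion is bounded
  # by the lattice constant 2/sqrt(3)
  s <- icosphere(3)
  fmm <- geodesic_distances(s, 1L)$distances
  dij <- dijkstra_oracle(s, 1L)
  expect_true(all(fmm <= dij * (1 + 1e-9)))
  expect_true(all(fmm >= dij * (sqrt(3) / 2 - 0.01)))
  # on a right-triangle grid the edge graph is tighter: within 10%
  g <- grid_mesh(21, 21, 1)
  fmm <- geodesic_distances(g, 1L)$distances
  dij <- dijkstra_oracle(g, 1L)
  expect_true(all(fmm <= dij * (1 + 1e-9)))
  expect_true(all(fmm >= dij * 0.90))
})

test_that("geodesic triangle inequality holds on a flat grid", {
  g <- grid_mesh(15, 15, 1)
  set.seed(42)
  n <- nrow(g$vertices)
  for (i in 1:10) {
    trip <- sample.int(n, 3)
    dab <- geodesic_distances(g, trip[1])$distances[trip[2]]
    dbc <- geodesic_distances(g, trip[2])$distances[trip[3]]
    dac <- geodesic_distances(g, trip[1])$distances[trip[3]]
    expect_lte(dac, (dab + dbc) * 1.02)
  }
})

test_that("map_to_surface snaps exactly, robustly, and breaks ties low", {
  m <- grid_mesh(5, 5, 1)
  expect_identical(map_to_surface(m$vertices[7, , drop = FALSE], m), 7L)
  expect_identical(map_to_surface(m$vertices[7, , drop = FALSE] +
                                    c(0.01, 0, 0), m), 7L)
  # equidistant between vertices 1 (0,0) and 2 (1,0): lowest index wins,
  # verified against a brute-force scan
  p <- matrix(c(0.5, 0, 0), 1, 3)
  d_all <- sqrt(rowSums(sweep(m$vertices, 2, p[1, ])^2))
  expect_identical(map_to_surface(p, m), which(d_all == min(d_all))[1])
  expect_identical(map_to_surface(p, m), 1L)
})

test_that("point clouds reconstruct to a surface that preserves geodesics", {
  # planar cloud: reconstruction passes through the points exactly
  set.seed(1)
  pts <- cbind(runif(500, 0, 50), runif(500, 0, 50), 0)
  s <- reconstruct_surface(point_cloud(pts))
  expect_s3_class(s, "surface_mesh")
  expect_identical(s$role, "S")
  expect_lt(max(abs(s$vertices[, 3])), 0.5)

  # cloud sampled from a mesh: landmark geodesics within 10% of the source
  liver <- liver_fixture()
  cl <- point_cloud(liver$mesh$vertices)
  rec <- reconstruct_surface(cl)
  set.seed(2)
  pairs <- matrix(sample.int(nrow(cl$points), 10), ncol = 2)
  for (r in seq_len(nrow(pairs))) {
    d0 <- suppressWarnings(
      geodesic_distances(liver$mesh, pairs[r, 1]))$distances[pairs[r, 2]]
    d1 <- suppressWarnings(
      geodesic_distances(rec, pairs[r, 1]))$distances[pairs[r, 2]]
    if (d0 > 50 && is.finite(d1)) expect_lt(abs(d1 - d0) / d0, 0.10)
  }

  expect_error(reconstruct_surface(point_cloud(cbind(1:3, 1:3, 1:3))),
               "reconstruction error")
  coll <- cbind(seq_len(60), seq_len(60), seq_len(60))
  expect_error(reconstruct_surface(point_cloud(coll)), "reconstruction error")
})

test_that("subsampled reconstruction perturbs landmark geodesics by < 10%", {
  liver <- liver_fixture4()
  m <- liver$mesh
  set.seed(3)
  keep <- sort(sample.int(nrow(m$vertices), round(0.3 * nrow(m$vertices))))
  rec <- reconstruct_surface(point_cloud(m$vertices[keep, ]))
  pairs <- matrix(sample(seq_along(keep), 8), ncol = 2)
  checked <- 0
  for (r in seq_len(nrow(pairs))) {
    d0 <- suppressWarnings(
      geodesic_distances(m, keep[pairs[r, 1]]))$distances[keep[pairs[r, 2]]]
    d1 <- suppressWarnings(
      geodesic_distances(rec, pairs[r, 1]))$distances[pairs[r, 2]]
    if (d0 > 80 && is.finite(d1)) {
      expect_lt(abs(d1 - d0) / d0, 0.10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})
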