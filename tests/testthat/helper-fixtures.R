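# shared fixtures, all generated in code

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),  # z = 0
             c(5, 6, 7), c(6, 8, 7),  # z = side
             c(1, 2, 5), c(2, 6, 5),  # y = 0
             c(3, 7, 4), c(4, 7, 8),  # y = side
             c(1, 5, 3), c(3, 5, 7),  # x = 0
             c(2, 4, 6), c(4, 8, 6))  # x = side
  surface_mesh(v, f)
}

# six disconnected axis-aligned squares: vertex normals = face normals
six_face_mesh <- function() {
  quad <- function(origin, du, dv) {
    p0 <- origin
    rbind(p0, p0 + du, p0 + du + dv, p0 + dv)
  }
  verts <- rbind(
    quad(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)),      # -z
    quad(c(0, 0, 2), c(1, 0, 0), c(0, 1, 0)),      # +z
    quad(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),      # -y
    quad(c(0, 2, 0), c(0, 0, 1), c(1, 0, 0)),      # +y
    quad(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0)),      # -x
    quad(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1))       # +x
  )
  faces <- do.call(rbind, lapply(0:5, function(k) {
    b <- 4 * k
    rbind(b + c(1, 2, 3), b + c(1, 3, 4))
  }))
  m <- structure(list(vertices = verts, triangles = faces, normals = NULL,
                      role = "M"), class = "surface_mesh")
  # skip closed-surface reorientation: faces already oriented outward-ish
  fn <- contourreg:::face_normals(verts, faces)
  nrm <- matrix(0, nrow(verts), 3)
  for (i in seq_len(nrow(faces)))
    for (k in 1:3) nrm[faces[i, k], ] <- fn[i, ]
  m$normals <- nrm
  m
}

rand_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  contourreg:::rotation_from_axis_angle(ax, runif(1, 0, pi))
}

# the liver fixture used across suites (built once per test session)
liver_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_liver(3)
    cache
  }
})

liver_fixture4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_liver(4)
    cache
  }
})

bench_config <- function(mesh, ...) {
  pipeline_config(d_ransac = 5, toldi_L = 8L, n_features = 150L,
                  toldi_radius = 0.06 * bbox_diagonal(mesh),
                  ransac_score = "rmse", ...)
}

# edge-graph Dijkstra oracle (igraph), independent of the fast-marching path
dijkstra_oracle <- function(mesh, source) {
  e <- contourreg:::mesh_edges(mesh$triangles)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  as.numeric(igraph::distances(g, v = source, weights = w))
}
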