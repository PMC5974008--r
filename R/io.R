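#' Read a surface mesh or point cloud from disk
#'
#' Supported formats: PLY (ascii and binary little-endian), OBJ, STL (ascii
#' and binary) and CSV point clouds with columns `x,y,z[,nx,ny,nz]`. A PLY
#' file without faces is returned as a [point_cloud()]. Coordinates are
#' assumed to be in millimetres.
#'
#' @param path file to read.
#' @param format `"ply"`, `"obj"`, `"stl"` or `"csv"`; inferred from the file
#'   extension when `NULL`.
#' @param role role tag passed to [surface_mesh()].
#' @return a [surface_mesh()] or a [point_cloud()].
#' @export
load_surface <- function(path, format = NULL, role = "M") {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  geom <- switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    csv = read_cloud_csv(path),
    stop("format error: unsupported format '", format, "'")
  )
  if (nrow(geom$vertices) == 0L) stop("input error: empty geometry in ", path)
  if (is.null(geom$faces) || nrow(geom$faces) == 0L)
    point_cloud(geom$vertices, geom$normals)
  else
    surface_mesh(geom$vertices, geom$faces, role = role)
}

#' Write a surface mesh or point cloud
#'
#' @param x a [surface_mesh()] or [point_cloud()].
#' @param path output file; the extension selects the format.
#' @param format as in [load_surface()].
#' @param binary write binary PLY/STL instead of ascii.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path, format = NULL, binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  v <- if (inherits(x, "point_cloud")) x$points else x$vertices
  f <- if (inherits(x, "point_cloud")) NULL else x$triangles
  switch(format,
    ply = write_ply(v, f, path, binary = binary),
    obj = write_obj(v, f, path),
    stl = write_stl(v, f, path, binary = binary),
    csv = write_cloud_csv(x, path),
    stop("format error: unsupported format '", format, "'")
  )
  invisible(path)
}

read_cloud_csv <- function(path) {
  d <- read.csv(path)
  names(d) <- tolower(names(d))
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("parse error: CSV point cloud needs x,y,z columns")
  nrm <- NULL
  if (all(c("nx", "ny", "nz") %in% names(d)))
    nrm <- as.matrix(d[, c("nx", "ny", "nz")])
  list(vertices = as.matrix(d[, c("x", "y", "z")]), faces = NULL, normals = nrm)
}

write_cloud_csv <- function(x, path) {
  p <- if (inherits(x, "point_cloud")) x$points else x$vertices
  d <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3])
  n <- x$normals
  if (!is.null(n)) { d$nx <- n[, 1]; d$ny <- n[, 2]; d$nz <- n[, 3] }
  write.csv(d, path, row.names = FALSE)
}

# ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!length(magic) || trimws(magic) != "ply") stop("parse error: not a PLY file")
  fmt <- NULL; elems <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("parse error: PLY header truncated")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        elems[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], type = tok[4])
      else
        elems[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("parse error: PLY format line missing")
  if (fmt == "ascii") read_ply_ascii(con, elems)
  else if (fmt == "binary_little_endian") read_ply_binary(con, elems)
  else stop("format error: unsupported PLY format ", fmt)
}

read_ply_ascii <- function(con, elems) {
  out <- list(vertices = NULL, faces = NULL, normals = NULL)
  for (en in names(elems)) {
    el <- elems[[en]]
    if (el$count == 0L) next
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count) stop("parse error: PLY data truncated")
    toks <- strsplit(trimws(lines), "\\s+")
    if (en == "vertex") {
      pn <- names(el$props)
      vals <- t(vapply(toks, function(x) as.numeric(x[seq_along(pn)]), numeric(length(pn))))
      if (length(pn) == 1L) vals <- matrix(vals, ncol = 1)
      colnames(vals) <- pn
      if (anyNA(vals[, c("x", "y", "z")])) stop("parse error: bad PLY vertex data")
      out$vertices <- vals[, c("x", "y", "z"), drop = FALSE]
      if (all(c("nx", "ny", "nz") %in% pn))
        out$normals <- vals[, c("nx", "ny", "nz"), drop = FALSE]
    } else if (en == "face") {
      faces <- lapply(toks, function(x) {
        n <- as.integer(x[1])
        if (length(x) < n + 1L) stop("parse error: bad PLY face row")
        as.integer(x[2:(n + 1)])
      })
      out$faces <- fan_triangulate(faces) + 1L
    }
  }
  out
}

ply_rtype <- function(type) {
  switch(type,
    float = list(what = "numeric", size = 4), float32 = list(what = "numeric", size = 4),
    double = list(what = "numeric", size = 8), float64 = list(what = "numeric", size = 8),
    char = list(what = "integer", size = 1), int8 = list(what = "integer", size = 1),
    uchar = list(what = "integer", size = 1), uint8 = list(what = "integer", size = 1),
    short = list(what = "integer", size = 2), int16 = list(what = "integer", size = 2),
    ushort = list(what = "integer", size = 2), uint16 = list(what = "integer", size = 2),
    int = list(what = "integer", size = 4), int32 = list(what = "integer", size = 4),
    uint = list(what = "integer", size = 4), uint32 = list(what = "integer", size = 4),
    stop("format error: unsupported PLY type ", type)
  )
}

read_ply_binary <- function(con, elems) {
  out <- list(vertices = NULL, faces = NULL, normals = NULL)
  rd <- function(type, n = 1) {
    rt <- ply_rtype(type)
    x <- readBin(con, rt$what, n = n, size = rt$size, endian = "little",
                 signed = !(rt$size < 4 && grepl("^u", type)))
    if (length(x) < n) stop("parse error: PLY data truncated")
    x
  }
  for (en in names(elems)) {
    el <- elems[[en]]
    if (el$count == 0L) next
    pn <- names(el$props)
    has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (!has_list) {
      types <- vapply(el$props, `[[`, "", "type")
      if (length(unique(types)) == 1L) {
        vals <- matrix(rd(types[1], el$count * length(pn)),
                       ncol = length(pn), byrow = TRUE)
      } else {
        vals <- matrix(0, el$count, length(pn))
        for (i in seq_len(el$count))
          for (j in seq_along(pn)) vals[i, j] <- rd(types[j], 1)
      }
      colnames(vals) <- pn
      if (en == "vertex") {
        out$vertices <- vals[, c("x", "y", "z"), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% pn))
          out$normals <- vals[, c("nx", "ny", "nz"), drop = FALSE]
      }
    } else {
      faces <- vector("list", el$count)
      lp <- el$props[[which(vapply(el$props, `[[`, TRUE, "list"))[1]]]
      for (i in seq_len(el$count)) {
        n <- rd(lp$count_type, 1)
        faces[[i]] <- rd(lp$type, n)
      }
      if (en == "face") out$faces <- fan_triangulate(faces) + 1L
    }
  }
  out
}

# polygon rows -> triangle fan, 0-based in, 0-based out
fan_triangulate <- function(faces) {
  tri <- lapply(faces, function(f) {
    if (length(f) < 3L) return(NULL)
    cbind(f[1], f[2:(length(f) - 1)], f[3:length(f)])
  })
  do.call(rbind, tri)
}

write_ply <- function(v, f, path, binary = FALSE) {
  nf <- if (is.null(f)) 0L else nrow(f)
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (nf > 0) sprintf("element face %d", nf),
           if (nf > 0) "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    if (nf > 0) {
      f0 <- t(f) - 1L
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
      }
    }
  } else {
    body <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE), collapse = " "))
    if (nf > 0)
      body <- c(body, apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("parse error: OBJ has no vertices")
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  if (anyNA(v)) stop("parse error: bad OBJ vertex data")
  faces <- NULL
  if (length(fl)) {
    faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      idx <- as.integer(vapply(strsplit(x[-1], "/"), `[[`, "", 1))
      idx - 1L
    })
    faces <- fan_triangulate(faces) + 1L
  }
  list(vertices = v, faces = faces, normals = NULL)
}

write_obj <- function(v, f, path) {
  lines <- sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  if (!is.null(f))
    lines <- c(lines, sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  close(con)
  txt <- rawToChar(head80[head80 != as.raw(0)][1:min(5, sum(head80 != as.raw(0)))])
  is_ascii <- grepl("^solid", txt) && is_ascii_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  merge_stl_vertices(tri)
}

is_ascii_stl <- function(path) {
  lines <- tryCatch(readLines(path, n = 50, warn = FALSE), error = function(e) character())
  any(grepl("facet normal", lines))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("vertex", lines, value = TRUE)
  if (!length(vl)) stop("parse error: STL has no vertices")
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  if (nrow(v) %% 3L != 0L) stop("parse error: STL vertex count not multiple of 3")
  v
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(n) || n < 1) stop("parse error: bad binary STL")
  v <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("parse error: STL data truncated")
    v[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  v
}

merge_stl_vertices <- function(tri_verts) {
  key <- apply(round(tri_verts, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri_verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces, normals = NULL)
}

write_stl <- function(v, f, path, binary = FALSE) {
  if (is.null(f)) stop("format error: STL requires triangles")
  fn <- face_normals(v, f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    lines <- c("solid contourreg")
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "  endloop", "endfacet")
    }
    writeLines(c(lines, "endsolid contourreg"), path)
  }
  invisible(path)
}
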