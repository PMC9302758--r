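#' Read a triangle mesh from OBJ, PLY or STL
#'
#' Coordinates are taken to be millimetres. OBJ `v`/`f` records are parsed
#' (with `v/vt/vn` face syntax tolerated); PLY may be `ascii` or
#' `binary_little_endian`; STL may be ascii or binary, and its duplicated
#' per-facet vertices are merged by coordinate hashing after snapping to a
#' 1e-6 mm grid (STL carries no shared topology). Faces with more than three
#' vertices are rejected: this package works on pure triangle meshes.
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; default guesses from the
#'   file extension.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("obj", "ply", "stl"))
      stop("cannot guess mesh format from extension of ", path)
  }
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl)) stop("OBJ file has no vertices: ", path)
  verts <- t(vapply(strsplit(sub("^v\\s+", "", vl), "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  faces <- lapply(strsplit(sub("^f\\s+", "", fl), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p, "/"), `[[`, "", 1))
  })
  nv <- lengths(faces)
  if (any(nv != 3L))
    stop("non-triangular face (", nv[which(nv != 3L)[1]], " vertices) at face ",
         which(nv != 3L)[1], " in ", path)
  tri_mesh(verts, do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# maskfit triangle mesh (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines terminated by \n
  header <- character(0)
  repeat {
    line <- read_bin_line(con)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 500) stop("PLY header not terminated in ", path)
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elems <- list(); cur <- NULL
  for (h in header) {
    p <- strsplit(trimws(h), "\\s+")[[1]]
    if (p[1] == "element") {
      cur <- p[2]
      elems[[cur]] <- list(count = as.integer(p[3]), props = list())
    } else if (p[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1]] <- p[-1]
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file lacks vertex/face elements: ", path)
  nv <- elems$vertex$count; nf <- elems$face$count
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    vp <- length(elems$vertex$props)
    vdat <- strsplit(trimws(rest[seq_len(nv)]), "\\s+")
    verts <- t(vapply(vdat, function(p) as.numeric(p[1:3]), numeric(3)))
    fdat <- strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+")
    faces <- lapply(fdat, function(p) {
      n <- as.integer(p[1])
      if (n != 3L) stop("non-triangular face (", n, " vertices) in ", path)
      as.integer(p[2:4]) + 1L
    })
    tri_mesh(verts, do.call(rbind, faces))
  } else if (fmt == "binary_little_endian") {
    ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                       short = 2, ushort = 2, int16 = 2, uint16 = 2,
                       int = 4, uint = 4, int32 = 4, uint32 = 4,
                       float = 4, float32 = 4, double = 8, float64 = 8)
    vprops <- elems$vertex$props
    verts <- matrix(NA_real_, nv, 3)
    prop_names <- vapply(vprops, function(p) p[2], "")
    for (i in seq_len(nv)) {
      for (j in seq_along(vprops)) {
        ty <- vprops[[j]][1]
        sz <- ply_type_size[[ty]]
        val <- if (ty %in% c("float", "float32", "double", "float64"))
          readBin(con, "double", 1, size = sz, endian = "little")
        else readBin(con, "integer", 1, size = sz, endian = "little")
        k <- match(prop_names[j], c("x", "y", "z"))
        if (!is.na(k)) verts[i, k] <- val
      }
    }
    fprops <- elems$face$props[[1]]  # list <count type> <index type> name
    cty <- fprops[2]; ity <- fprops[3]
    csz <- ply_type_size[[cty]]; isz <- ply_type_size[[ity]]
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", 1, size = csz, endian = "little", signed = csz > 2)
      idx <- readBin(con, "integer", n, size = isz, endian = "little")
      if (n != 3L) stop("non-triangular face (", n, " vertices) in ", path)
      faces[i, ] <- idx + 1L
    }
    tri_mesh(verts, faces)
  } else stop("unsupported PLY format: ", fmt)
}

read_bin_line <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b) || b == as.raw(10)) break
    bytes <- c(bytes, b)
  }
  trimws(rawToChar(bytes))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment maskfit triangle mesh (mm)",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", min(80, sz))
  is_ascii <- startsWith(trimws(rawToChar(head80[1:min(5, length(head80))])), "solid")
  if (is_ascii) {
    # an STL starting with "solid" can still be binary; verify by facet count
    ntri_guess <- if (sz >= 84) {
      seek(con, 80)
      readBin(con, "integer", 1, size = 4, endian = "little")
    } else -1
    if (sz == 84 + 50 * ntri_guess) is_ascii <- FALSE
  }
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    pts <- t(vapply(strsplit(sub("^vertex\\s+", "", vl), "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
  } else {
    seek(con, 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    pts <- matrix(NA_real_, 3 * ntri, 3)
    for (i in seq_len(ntri)) {
      readBin(con, "numeric", 3, size = 4, endian = "little")  # facet normal
      v <- readBin(con, "numeric", 9, size = 4, endian = "little")
      pts[3 * i - 2:0, ] <- matrix(v, 3, 3, byrow = TRUE)
      readBin(con, "integer", 1, size = 2, endian = "little")  # attribute bytes
    }
  }
  if (nrow(pts) %% 3 != 0 || nrow(pts) == 0) stop("malformed STL file: ", path)
  merge_stl_soup(pts)
}

# Merge STL's per-facet vertex soup into shared topology: snap to a 1e-6 mm
# grid and hash exact snapped coordinates.
merge_stl_soup <- function(pts, snap = 1e-6) {
  key <- apply(round(pts / snap), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  verts <- pts[uniq, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write a mesh (and optional nodal pressure field) to standard formats
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"obj"`, `"ply"`, or `"vtk"` (legacy ascii unstructured grid;
#'   used for pressure visualization).
#' @param pressure optional numeric vector, one value per vertex (MPa); written
#'   as the VTK `POINT_DATA` scalar field `contact_pressure_MPa`. Ignored for
#'   OBJ/PLY.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("obj", "ply", "vtk"), pressure = NULL) {
  format <- match.arg(format)
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk(mesh, path, pressure))
  invisible(path)
}

write_vtk <- function(mesh, path, pressure = NULL) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "maskfit face-mask contact pressure (mm, MPa)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nt, 4L * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  if (!is.null(pressure)) {
    stopifnot(length(pressure) == nv)
    writeLines(c(sprintf("POINT_DATA %d", nv),
                 "SCALARS contact_pressure_MPa double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", pressure), con)
  }
  invisible(path)
}

#' Read or write landmark annotations
#'
#' Landmarks are a JSON object mapping names to 1-based vertex indices, e.g.
#' `{"sellion": 152, "pronasale": 90}`.
#'
#' @param path JSON file path.
#' @return named integer vector of vertex indices.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path)
  vapply(lm, as.integer, integer(1))
}

#' @rdname read_landmarks
#' @param landmarks named integer vector.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(as.list(landmarks), path, auto_unbox = TRUE)
  invisible(path)
}
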