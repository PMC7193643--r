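#' Read and write surface meshes
#'
#' PLY (binary little-endian, `double` precision, optional per-vertex
#' `distance` property — the only format that preserves scalars and
#' round-trips vertices bit-exactly), ASCII STL (triangle soup: vertex
#' sharing is lost, coordinates are preserved to full precision) and
#' Wavefront OBJ (indexed, scalars dropped with a warning).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format `"ply"`, `"stl"` or `"obj"`; guessed from the file
#'   extension when missing.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns a
#'   [surface_mesh()].
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- mesh_format(path, format)
  switch(format,
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop_ts("file not found: ", path)
  format <- mesh_format(path, format)
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path))
}

mesh_format <- function(path, format) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "stl", "obj"))
    stop_ts("unknown mesh format: ", format)
  format
}

write_ply <- function(mesh, path) {
  has_sc <- !is.null(mesh$scalars)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           if (has_sc) "property double distance",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vdat <- t(if (has_sc) cbind(mesh$vertices, mesh$scalars) else
    mesh$vertices)
  writeBin(as.vector(vdat), con, size = 8, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3L), con)
    writeBin(mesh$faces[i, ] - 1L, con, size = 4, endian = "little")
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(line) == 0) stop_ts("malformed PLY header in ", path)
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub(".*vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face ", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  # vertex property names/types in declared order
  vstart <- grep("^element vertex", hdr)
  vend <- grep("^element face", hdr)
  vprops <- grep("^property ", hdr[(vstart + 1):(vend - 1)], value = TRUE)
  vp <- do.call(rbind, strsplit(vprops, " +"))
  types <- vp[, 2]
  names <- vp[, 3]
  sizes <- c(float = 4L, double = 8L)[types]
  if (anyNA(sizes)) stop_ts("unsupported PLY vertex property type")
  if (binary) {
    vdat <- matrix(NA_real_, nrow = nv, ncol = length(names))
    buf <- readBin(con, "raw", n = nv * sum(sizes))
    off <- 0L
    rowbytes <- sum(sizes)
    for (j in seq_along(names)) {
      idx <- as.vector(outer(seq_len(sizes[j]), (seq_len(nv) - 1L) * rowbytes,
                             "+")) + off
      vdat[, j] <- readBin(buf[idx], "double", n = nv, size = sizes[j],
                           endian = "little")
      off <- off + sizes[j]
    }
    faces <- matrix(0L, nrow = nf, ncol = 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stop_ts("only triangular PLY faces are supported")
      faces[i, ] <- readBin(con, "integer", n = 3, size = 4,
                            endian = "little") + 1L
    }
  } else {
    txt <- readLines(con)
    vdat <- do.call(rbind,
                    lapply(strsplit(trimws(txt[seq_len(nv)]), " +"),
                           as.numeric))
    frows <- strsplit(trimws(txt[nv + seq_len(nf)]), " +")
    faces <- do.call(rbind, lapply(frows, function(r) {
      if (as.integer(r[1]) != 3L)
        stop_ts("only triangular PLY faces are supported")
      as.integer(r[2:4]) + 1L
    }))
  }
  sc <- if ("distance" %in% names) vdat[, match("distance", names)]
  surface_mesh(vdat[, match(c("x", "y", "z"), names), drop = FALSE],
               faces, scalars = sc)
}

write_stl <- function(mesh, path) {
  if (!is.null(mesh$scalars))
    warning("STL cannot store per-vertex scalars; they were dropped",
            call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  n <- face_normals(mesh)
  cat("solid mesh\n", file = con)
  for (i in seq_len(nrow(mesh$faces))) {
    cat(sprintf("facet normal %.17g %.17g %.17g\n", n[i, 1], n[i, 2],
                n[i, 3]),
        " outer loop\n", sep = "", file = con)
    for (k in 1:3) {
      v <- mesh$vertices[mesh$faces[i, k], ]
      cat(sprintf("  vertex %.17g %.17g %.17g\n", v[1], v[2], v[3]),
          file = con)
    }
    cat(" endloop\nendfacet\n", file = con)
  }
  cat("endsolid mesh\n", file = con)
}

read_stl <- function(path) {
  txt <- readLines(path)
  vlines <- grep("^\\s*vertex ", txt, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0)
    stop_ts("malformed ASCII STL: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), " +"), function(r)
    as.numeric(r[2:4])))
  nf <- nrow(v) / 3
  surface_mesh(v, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

write_obj <- function(mesh, path) {
  if (!is.null(mesh$scalars))
    warning("OBJ cannot store per-vertex scalars; they were dropped",
            call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_obj <- function(path) {
  txt <- readLines(path)
  vl <- strsplit(trimws(grep("^v ", txt, value = TRUE)), " +")
  fl <- strsplit(trimws(grep("^f ", txt, value = TRUE)), " +")
  v <- do.call(rbind, lapply(vl, function(r) as.numeric(r[2:4])))
  f <- do.call(rbind, lapply(fl, function(r)
    as.integer(sub("/.*", "", r[2:4]))))
  surface_mesh(v, f)
}
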