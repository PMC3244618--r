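#' Load a vessel mesh from OBJ or STL
#'
#' Reads a Wavefront OBJ (`v`/`f` records; polygonal faces are fan-
#' triangulated; 1-based on-disk indices) or a binary STL file. Normals are
#' always recomputed from the geometry and re-oriented toward the lumen
#' interior by per-triangle ray-parity tests (see [orient_inward()]), since
#' file winding order is unreliable. STL soup vertices that coincide exactly
#' are merged so connectivity is recovered.
#'
#' @param path file path.
#' @param format `"obj"` or `"stl"`; default guesses from the extension.
#' @return a [vessel_mesh()].
#' @export
load_mesh <- function(path, format = c("auto", "obj", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", stl = "stl",
                     stop(sprintf("cannot guess mesh format from '%s'", path),
                          call. = FALSE))
  }
  raw <- switch(format, obj = read_obj(path), stl = read_stl(path))
  if (nrow(raw$triangles) == 0L) stop("empty mesh: no triangles", call. = FALSE)
  orient_inward(vessel_mesh(raw$vertices, raw$triangles))
}

#' Write a vessel mesh to OBJ or STL
#'
#' OBJ is written in ASCII with 9-significant-digit coordinates (so a
#' write/load round trip preserves vertices to well under 1e-6 mm); STL is
#' the standard binary 50-byte-per-facet layout (float32 coordinates).
#'
#' @param mesh a [vessel_mesh()].
#' @param path output file path.
#' @param format `"obj"` or `"stl"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "stl")) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", stl = "stl",
                     stop(sprintf("cannot guess mesh format from '%s'", path),
                          call. = FALSE))
  }
  switch(format, obj = write_obj(mesh, path), stl = write_stl(mesh, path))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ parse error: no vertices", call. = FALSE)
  verts <- t(vapply(strsplit(sub("^v\\s+", "", vl), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[1:3]))
    if (anyNA(x)) stop("OBJ parse error: bad vertex record", call. = FALSE)
    x
  }, numeric(3)))
  tris <- list()
  for (rec in strsplit(sub("^f\\s+", "", fl), "\\s+")) {
    # take the vertex index before any '/'; fan-triangulate polygons
    idx <- suppressWarnings(as.integer(sub("/.*$", "", rec)))
    if (anyNA(idx) || length(idx) < 3L) {
      stop("OBJ parse error: bad face record", call. = FALSE)
    }
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    for (k in seq_len(length(idx) - 2L)) {
      tris[[length(tris) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
  }
  list(vertices = verts,
       triangles = if (length(tris)) do.call(rbind, tris)
                   else matrix(integer(), 0L, 3L))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  if (length(header) < 80L) stop("STL parse error: truncated header", call. = FALSE)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(ntri) != 1L || is.na(ntri) || ntri <= 0L) {
    stop("STL parse error: bad facet count", call. = FALSE)
  }
  payload <- readBin(con, "raw", 50L * ntri)
  if (length(payload) < 50L * ntri) {
    stop("STL parse error: truncated facet data", call. = FALSE)
  }
  dim(payload) <- c(50L, ntri)
  coords <- matrix(0, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(payload[1:48, i], "numeric", 12L, size = 4L,
                    endian = "little")
    coords[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  # merge bit-identical vertices to recover connectivity
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "\r")
  uniq <- !duplicated(key)
  ids <- match(key, key[uniq])
  list(vertices = coords[uniq, , drop = FALSE],
       triangles = matrix(ids, ntri, 3L, byrow = TRUE))
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  ntri <- nrow(mesh$triangles)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  for (i in seq_len(ntri)) {
    tri <- mesh$triangles[i, ]
    vals <- c(mesh$normals[i, ],
              t(mesh$vertices[tri, , drop = FALSE]))
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}
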