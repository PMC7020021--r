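#' Read a surface mesh from STL or PLY
#'
#' Accepts ASCII and binary STL and ASCII PLY. Coordinates are assumed to
#' be in millimetres. STL triangle soup is welded back into shared vertices
#' by exact coordinate match.
#'
#' @param path file path; format chosen by extension (`.stl`, `.ply`).
#' @param weld merge exactly coincident vertices (default `TRUE`).
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path, weld = TRUE) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unsupported mesh format '", ext, "': ", path)
  )
  if (weld) mesh <- weld_vertices(mesh)
  mesh
}

weld_vertices <- function(mesh) {
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  idx <- match(key, key)
  keep <- sort(unique(idx))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[idx[mesh$faces]], ncol = 3)
  surface_mesh(mesh$vertices[keep, , drop = FALSE], faces)
}

stl_is_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  # binary iff the triangle count matches the file size
  isTRUE(abs(size - expected) < 1)
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  }
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
  if (anyNA(coords)) stop("malformed ASCII STL (non-numeric vertex): ", path)
  V <- t(coords)
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(n) || n < 1) stop("malformed binary STL: ", path)
  # each 50-byte record: 12 little-endian floats + 2 attribute bytes
  body <- readBin(con, "raw", n * 50)
  if (length(body) < n * 50) stop("truncated binary STL: ", path)
  dim(body) <- c(50, n)
  floats <- body[1:48, , drop = FALSE]
  vals <- readBin(as.raw(floats), "numeric", n * 12, size = 4,
                  endian = "little")
  rec <- matrix(vals, nrow = 12)  # per triangle: normal (3) + 3 vertices
  V <- matrix(as.numeric(rec[4:12, ]), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop("malformed PLY: ", path)
  }
  if (!grepl("ascii", lines[2])) stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY (no end_header): ", path)
  header <- trimws(lines[seq_len(endh)])
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY: ", path)
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(ftok, function(t) {
    k <- as.integer(t[1])
    if (is.na(k) || k != 3L) stop("only triangular PLY faces are supported")
    as.integer(t[2:4]) + 1L
  }, integer(3)))
  surface_mesh(V, F)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (`.stl` or `.ply`).
#' @param binary for STL, write the binary dialect (default `TRUE`); PLY is
#'   always ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path)
  } else if (ext == "ply") {
    write_ply(mesh, path)
  } else {
    stop("unsupported mesh format '", ext, "': ", path)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- triangle_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cheekmorph", con)
  for (i in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2], N[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      v <- V[F[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid cheekmorph", con)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- triangle_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "cheekmorph binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    rec <- c(N[i, ], t(V[F[i, ], , drop = FALSE]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

write_ply <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(V)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}
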