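#' Read and write PLY meshes
#'
#' `write_ply` writes a binary little-endian PLY file with double-precision
#' vertex coordinates (lossless round trip); an optional per-vertex scalar is
#' stored as a `quality` property. `read_ply` reads ASCII and binary
#' little-endian PLY files, keeping `x`, `y`, `z` (and `quality` when present)
#' and skipping other vertex properties.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @param scalar optional numeric per-vertex scalar to store as `quality`.
#' @param ascii write ASCII PLY instead of binary.
#' @return `write_ply` returns `path` invisibly. `read_ply` returns a
#'   [triangle_mesh()]; a `quality` property, if present, is attached as
#'   attribute `scalar`.
#' @export
write_ply <- function(mesh, path, scalar = NULL, ascii = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(scalar)) stopifnot(length(scalar) == nv)
  hdr <- c("ply",
           if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
           "comment endocastr mesh",
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           if (!is.null(scalar)) "property double quality",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vdat <- mesh$vertices
  if (!is.null(scalar)) vdat <- cbind(vdat, as.numeric(scalar))
  f0 <- mesh$faces - 1L
  if (ascii) {
    writeLines(apply(vdat, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con, sep = "\n")
    writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con, sep = "\n")
  } else {
    writeBin(as.vector(t(vdat)), con, size = 8, endian = "little")
    if (nf > 0) {
      # interleave uchar count with 3 int32 indices
      raw_counts <- as.raw(rep(3L, nf))
      idx <- writeBin(as.integer(t(f0)), raw(), size = 4, endian = "little")
      idx <- matrix(idx, nrow = 12)
      block <- rbind(matrix(raw_counts, nrow = 1), idx)
      writeBin(as.vector(block), con)
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header")
    hdr <- c(hdr, line)
    if (identical(trimws(line), "end_header")) break
    if (length(hdr) > 500) stop("malformed PLY header")
  }
  if (!identical(trimws(hdr[1]), "ply")) stop("not a PLY file")
  fmt <- grep("^format", hdr, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)

  # parse elements and their properties
  elems <- list()
  cur <- NULL
  for (line in hdr) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) == 0) next
    if (toks[1] == "element") {
      cur <- toks[2]
      elems[[cur]] <- list(count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, list(toks[-1]))
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file must contain vertex and face elements")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4, float = 4,
                 float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n) {
    sz <- type_size[[type]]
    if (is.null(sz)) stop("unsupported PLY property type: ", type)
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", type)))
  }

  nv <- elems$vertex$count
  vprops <- elems$vertex$props
  pnames <- vapply(vprops, function(p) p[length(p)], "")
  if (binary) {
    sizes <- vapply(vprops, function(p) type_size[[p[1]]], 0)
    stride <- sum(sizes)
    rawdat <- readBin(con, "raw", n = stride * nv)
    offs <- cumsum(c(0, sizes[-length(sizes)]))
    cols <- lapply(seq_along(vprops), function(i) {
      type <- vprops[[i]][1]
      sz <- sizes[i]
      sel <- as.vector(outer(seq_len(sz), (seq_len(nv) - 1) * stride + offs[i],
                             "+"))
      bytes <- rawdat[sel]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(bytes, "double", n = nv, size = sz, endian = "little")
      else
        readBin(bytes, "integer", n = nv, size = sz, endian = "little",
                signed = !(sz < 4 && grepl("^u", type)))
    })
  } else {
    vals <- scan(con, what = numeric(), n = nv * length(vprops), quiet = TRUE)
    m <- matrix(vals, ncol = length(vprops), byrow = TRUE)
    cols <- lapply(seq_along(vprops), function(i) m[, i])
  }
  names(cols) <- pnames
  if (!all(c("x", "y", "z") %in% pnames)) stop("PLY vertex lacks x/y/z")
  v <- cbind(cols$x, cols$y, cols$z)

  nf <- elems$face$count
  fprop <- elems$face$props[[1]]
  if (fprop[1] != "list") stop("PLY face element must be a list property")
  if (binary) {
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- read_scalar(fprop[2], 1)
      idx <- read_scalar(fprop[3], cnt)
      if (cnt != 3) stop("only triangle faces are supported")
      faces[i, ] <- idx
    }
  } else {
    vals <- scan(con, what = numeric(), quiet = TRUE)
    faces <- matrix(0L, nf, 3)
    pos <- 1
    for (i in seq_len(nf)) {
      cnt <- vals[pos]
      if (cnt != 3) stop("only triangle faces are supported")
      faces[i, ] <- vals[pos + 1:3]
      pos <- pos + cnt + 1
    }
  }
  mesh <- triangle_mesh(v, faces + 1L)
  if ("quality" %in% pnames) attr(mesh, "scalar") <- cols$quality
  mesh
}

#' Read and write OFF meshes
#'
#' Plain ASCII OFF triangle meshes.
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @return `write_off` returns `path` invisibly; `read_off` a
#'   [triangle_mesh()].
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  f0 <- mesh$faces - 1L
  writeLines(paste(3L, f0[, 1], f0[, 2], f0[, 3]), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", trimws(lines[1]))) stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtok <- strsplit(trimws(lines[3:(2 + nv)]), "\\s+")
  v <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  ftok <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
  f <- t(vapply(ftok, function(t) {
    if (as.integer(t[1]) != 3) stop("only triangle faces are supported")
    as.integer(t[2:4])
  }, integer(3)))
  triangle_mesh(v, f + 1L)
}
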