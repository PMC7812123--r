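#' Rigid/similarity transform in 3D
#'
#' Represents the map \eqn{x \mapsto s R x + t} with a proper rotation
#' \eqn{R} (3x3, det = +1), a translation \eqn{t} in mm and a uniform
#' scale \eqn{s > 0}. Volume registration fixes \eqn{s = 1}; mesh alignment
#' (see [align_rigid_scale()]) estimates it.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation in mm.
#' @param scale positive uniform scale factor.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  scale <- as.numeric(scale)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
            length(scale) == 1, is.finite(scale), scale > 0,
            all(is.finite(rotation)), all(is.finite(translation)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("similarity_transform: scale", format(x$scale), "\n")
  cat("  translation (mm):", format(x$translation, digits = 5), "\n")
  ang <- rotation_angle_deg(x$rotation)
  cat("  rotation angle (deg):", format(ang, digits = 5), "\n")
  invisible(x)
}

#' Rotation matrix from Euler angles (degrees)
#'
#' Composes \eqn{R = R_z R_y R_x}, angles in degrees.
#'
#' @param x,y,z rotation angles about the x, y and z axes in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(x = 0, y = 0, z = 0) {
  r <- pi / 180
  cx <- cos(x * r); sx <- sin(x * r)
  cy <- cos(y * r); sy <- sin(y * r)
  cz <- cos(z * r); sz <- sin(z * r)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Total rotation angle of a rotation matrix, in degrees
#' @param R 3x3 rotation matrix.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Apply a similarity transform to points
#' @param transform a [similarity_transform()].
#' @param points n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  points <- as_points(points)
  out <- points %*% t(transform$rotation) * transform$scale
  sweep(out, 2, transform$translation, "+")
}

#' Compose two similarity transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first,
#' then `a`.
#' @param a,b [similarity_transform()] objects.
#' @return the composed [similarity_transform()].
#' @export
compose_transform <- function(a, b) {
  similarity_transform(rotation = a$rotation %*% b$rotation,
                       translation = a$scale * as.vector(a$rotation %*% b$translation) +
                         a$translation,
                       scale = a$scale * b$scale)
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return the inverse [similarity_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(rotation = Rt,
                       translation = -as.vector(Rt %*% transform$translation) /
                         transform$scale,
                       scale = 1 / transform$scale)
}

#' Convert a similarity transform to a 4x4 homogeneous matrix
#' @param transform a [similarity_transform()].
#' @return 4x4 matrix.
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$scale * transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Build a similarity transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix whose upper-left block is `scale * rotation`.
#' @return a [similarity_transform()].
#' @export
transform_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  A <- m[1:3, 1:3]
  s <- det(A)^(1 / 3)
  if (!is.finite(s) || s <= 0) stop("matrix is not a similarity transform")
  similarity_transform(rotation = A / s, translation = m[1:3, 4], scale = s)
}

#' Write/read a transform as a plain-text 4x4 matrix (row-major, mm)
#' @param transform a [similarity_transform()].
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [similarity_transform()].
#' @export
write_transform <- function(transform, path) {
  m <- transform_matrix(transform)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 4) stop("transform file must have 4 rows")
  m <- t(vapply(rows, function(r) as.numeric(r), numeric(4)))
  transform_from_matrix(m)
}

# internal: coerce to an n x 3 double matrix
as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("points must be n x 3")
  storage.mode(x) <- "double"
  x
}

# internal: scoped RNG seed that restores the caller's RNG state
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()),
    envir = env)
  invisible(seed)
}
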