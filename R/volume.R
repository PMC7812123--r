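#' 3D scalar volume image
#'
#' A 3D scalar grid with voxel spacing and world origin in mm, RAS axes.
#' Voxel centers sit at `origin + (index - 1) * spacing` (1-based R indices),
#' i.e. the first voxel center is at `origin`.
#'
#' @param values 3D numeric array.
#' @param spacing length-3 positive voxel spacing in mm.
#' @param origin length-3 world position (mm) of the first voxel center.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3,
            all(is.finite(spacing)), all(spacing > 0), all(is.finite(origin)))
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_image: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat("  origin (mm):", format(x$origin, digits = 5), "\n")
  cat("  intensity range:", format(range(x$values), digits = 5), "\n")
  invisible(x)
}

#' World coordinates of all voxel centers
#' @param volume a [volume_image()].
#' @return n x 3 matrix (mm), voxels in R array order.
#' @export
voxel_centers <- function(volume) {
  d <- dim(volume$values)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  sweep(sweep(as.matrix(g) - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

# internal: world mm -> continuous 0-based voxel coordinates
world_to_voxel <- function(volume, points) {
  sweep(sweep(as_points(points), 2, volume$origin, "-"), 2, volume$spacing,
        "/")
}

#' Sample a volume at world points by trilinear interpolation
#' @param volume a [volume_image()].
#' @param points n x 3 matrix of world points (mm).
#' @param background value for points outside the grid (default `NA`).
#' @param clamp if `TRUE`, clamp sample positions to the grid instead of
#'   returning `background`.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(volume, points, background = NA_real_,
                          clamp = FALSE) {
  pts <- world_to_voxel(volume, points)
  cpp_trilinear(as.vector(volume$values), dim(volume$values), pts,
                as.numeric(background), clamp)
}

#' Resample a volume onto a reference grid under a transform
#'
#' The transform maps moving-image world coordinates into the reference frame;
#' each reference voxel center is pulled back through its inverse and the
#' moving image is sampled by trilinear interpolation.
#'
#' @param image the moving [volume_image()].
#' @param transform a [similarity_transform()] mapping `image` world
#'   coordinates into the reference frame.
#' @param reference a [volume_image()] providing the output grid.
#' @param background fill value for out-of-field voxels.
#' @return a [volume_image()] on the reference grid.
#' @export
resample_volume <- function(image, transform = similarity_transform(),
                            reference = image, background = 0) {
  d <- dim(reference$values)
  if (any(d < 2)) stop("degenerate reference grid")
  pts <- voxel_centers(reference)
  src <- apply_transform(invert_transform(transform), pts)
  vals <- sample_volume(image, src, background = as.numeric(background))
  volume_image(array(vals, d), reference$spacing, reference$origin)
}

#' Read/write volumes as NIfTI
#'
#' Volumes are stored with an axis-aligned RAS affine built from spacing and
#' origin. `read_volume` accepts any NIfTI whose rotation part is axis-aligned
#' and positive.
#' @param volume a [volume_image()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [volume_image()].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dircos <- sweep(rot, 2, spacing, "/")
  if (max(abs(dircos - diag(3))) > 1e-4)
    stop("read_volume supports axis-aligned RAS volumes only")
  volume_image(array(as.numeric(img), dim(img)[1:3]), spacing, aff[1:3, 4])
}
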