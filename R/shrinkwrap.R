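#' Settings for deformable-sphere (shrink-wrap) surface extraction
#'
#' @param direction `"inward"` deforms an enclosing sphere onto the outside of
#'   a bright object (brain hull); `"outward"` inflates a sphere placed inside
#'   a cavity onto its inner wall (endocast).
#' @param step_size maximum vertex displacement per iteration (mm).
#' @param smoothing_weight Laplacian blend weight in `[0, 1)`; higher values
#'   bridge narrow grooves instead of entering them.
#' @param max_iterations iteration cap.
#' @param convergence_tol stop when the largest vertex displacement in an
#'   iteration falls below this (mm).
#' @param target_isovalue intensity level the surface settles on.
#' @param subdivisions icosphere subdivision level of the seed sphere
#'   (level L has `20 * 4^L` faces).
#' @return list of class `shrink_wrap_settings`.
#' @export
shrink_wrap_settings <- function(direction = c("inward", "outward"),
                                 step_size = 1, smoothing_weight = 0.25,
                                 max_iterations = 400,
                                 convergence_tol = 0.01,
                                 target_isovalue = 0.5,
                                 subdivisions = 5) {
  direction <- match.arg(direction)
  stopifnot(step_size > 0, smoothing_weight >= 0, smoothing_weight < 1,
            convergence_tol > 0, max_iterations >= 1, subdivisions >= 1)
  structure(list(direction = direction, step_size = step_size,
                 smoothing_weight = smoothing_weight,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 target_isovalue = target_isovalue,
                 subdivisions = as.integer(subdivisions)),
            class = "shrink_wrap_settings")
}

#' Deformable-sphere segmentation of an isosurface
#'
#' A subdivided icosahedron seed sphere is deformed iteratively: every vertex
#' moves along its normal by a step proportional to the signed intensity
#' mismatch at its position (clamped to `step_size`), then positions are
#' blended with the neighbour average (Laplacian smoothing weighted by
#' `smoothing_weight`). Inward mode requires the seed sphere to strictly
#' enclose the target surface; outward mode requires it strictly inside the
#' cavity. Iteration stops when the maximum displacement drops below
#' `convergence_tol` or after `max_iterations`.
#'
#' @param volume a [volume_image()].
#' @param seed_center sphere center (mm, world).
#' @param seed_radius sphere radius (mm).
#' @param settings a [shrink_wrap_settings()].
#' @return a watertight [triangle_mesh()] (genus 0, `20 * 4^subdivisions`
#'   faces) with attributes `convergence` (data frame of iteration and max
#'   displacement) and `converged`.
#' @export
shrink_wrap <- function(volume, seed_center, seed_radius, settings) {
  stopifnot(inherits(settings, "shrink_wrap_settings"))
  inward <- settings$direction == "inward"
  d <- dim(volume$values)
  lo <- volume$origin - volume$spacing
  hi <- volume$origin + d * volume$spacing
  iso <- settings$target_isovalue
  rng <- range(volume$values)
  halfspan <- max((rng[2] - rng[1]) / 2, 1e-12)

  # containment precondition
  cval <- sample_volume(volume, matrix(seed_center, 1), clamp = TRUE)
  if (inward) {
    fg <- which(volume$values >= iso, arr.ind = TRUE)
    if (nrow(fg) == 0) stop("no foreground at the target isovalue")
    w <- sweep(sweep(fg - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
    if (sqrt(max(rowSums(sweep(w, 2, seed_center, "-")^2))) >= seed_radius)
      stop("inward mode: seed sphere must strictly enclose the foreground")
  } else {
    if (is.na(cval) || cval >= iso)
      stop("outward mode: seed center must lie inside the cavity (below the isovalue)")
  }

  mesh <- icosphere(settings$subdivisions, seed_center, seed_radius)
  # neighbour structure for Laplacian smoothing
  e <- mesh_edges(mesh)
  nbr_i <- c(e[, 1], e[, 2])
  nbr_j <- c(e[, 2], e[, 1])
  deg <- tabulate(nbr_i, nbins = nrow(mesh$vertices))
  v <- mesh$vertices
  w <- settings$smoothing_weight
  log_it <- integer(0)
  log_disp <- numeric(0)
  converged <- FALSE

  for (it in seq_len(settings$max_iterations)) {
    n <- vertex_normals_of(v, mesh$faces)
    I <- sample_volume(volume_ref(volume), v, clamp = TRUE)
    f <- pmin(1, pmax(-1, (iso - I) / halfspan))
    disp <- if (inward) -n * (settings$step_size * f)
            else n * (settings$step_size * f)
    v1 <- v + disp
    if (w > 0) {
      avg <- rowsum(v1[nbr_j, , drop = FALSE], nbr_i, reorder = TRUE) / deg
      v1 <- (1 - w) * v1 + w * avg
    }
    moved <- sqrt(max(rowSums((v1 - v)^2)))
    v <- v1
    log_it <- c(log_it, it)
    log_disp <- c(log_disp, moved)
    if (!inward && (any(v < rep(lo, each = nrow(v))) ||
                    any(v > rep(hi, each = nrow(v)))))
      stop("shrink-wrap surface escaped the volume bounds")
    if (moved < settings$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  out <- triangle_mesh(v, mesh$faces)
  attr(out, "convergence") <- data.frame(iteration = log_it,
                                         max_displacement = log_disp)
  attr(out, "converged") <- converged
  if (!converged)
    warning("shrink_wrap reached max_iterations without converging; ",
            "returning best-so-far surface")
  out
}

# internal: vertex normals for raw vertex/face arrays
vertex_normals_of <- function(v, f) {
  vertex_normals(structure(list(vertices = v, faces = f),
                           class = "triangle_mesh"))
}

# internal: identity helper so sample_volume sees a volume_image
volume_ref <- function(volume) volume

#' Brain hull extraction from a binary brain mask
#'
#' Inward shrink-wrap of the mask: a simplified envelope of the brain surface
#' that bridges fine detail while keeping sulcal grooves of the phantom width
#' visible as depressions. The default smoothing weight is chosen so grooves
#' of width >= 2 voxels remain detectable by [trace_ravines()].
#'
#' @param mri_volume the intensity volume (only used for its grid when `mask`
#'   is given separately).
#' @param brain_mask binary [volume_image()] (1 = brain).
#' @param settings optional [shrink_wrap_settings()]; defaults to inward mode
#'   with `smoothing_weight = 0.25` and a step of half the smallest voxel.
#' @return a watertight [triangle_mesh()].
#' @export
brain_hull <- function(mri_volume, brain_mask = NULL, settings = NULL) {
  mask <- if (is.null(brain_mask)) mri_volume else brain_mask
  if (max(mask$values) <= min(mask$values)) stop("empty brain mask")
  if (is.null(settings)) {
    rng <- range(mask$values)
    # isovalue slightly below midrange biases the surface a fraction of a
    # voxel outward, so the hull encloses the voxel mask
    settings <- shrink_wrap_settings("inward",
                                     step_size = min(mask$spacing) / 2,
                                     smoothing_weight = 0.25,
                                     target_isovalue = rng[1] +
                                       0.35 * (rng[2] - rng[1]))
  }
  fg <- which(mask$values >= settings$target_isovalue, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty brain mask")
  w <- sweep(sweep(fg - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  center <- colMeans(w)
  radius <- sqrt(max(rowSums(sweep(w, 2, center, "-")^2))) +
    2 * max(mask$spacing)
  shrink_wrap(mask, center, radius, settings)
}

#' Endocast extraction from a CT-like volume
#'
#' Outward shrink-wrap from a small sphere placed inside the braincase cavity
#' onto the inner table of the bone.
#'
#' @param ct_volume a [volume_image()] with bright bone.
#' @param seed_center point inside the cavity (mm); defaults to the volume
#'   center.
#' @param settings optional [shrink_wrap_settings()]; defaults to outward mode
#'   with the isovalue halfway between cavity and bone intensities.
#' @return a watertight [triangle_mesh()].
#' @export
endocast_surface <- function(ct_volume, seed_center = NULL, settings = NULL) {
  d <- dim(ct_volume$values)
  if (is.null(seed_center))
    seed_center <- ct_volume$origin + (d - 1) / 2 * ct_volume$spacing
  if (is.null(settings))
    settings <- shrink_wrap_settings("outward",
                                     step_size = min(ct_volume$spacing) / 2,
                                     smoothing_weight = 0.25,
                                     target_isovalue = 0.5 *
                                       (max(ct_volume$values) +
                                          min(ct_volume$values)))
  shrink_wrap(ct_volume, seed_center, min(ct_volume$spacing) * 5, settings)
}
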