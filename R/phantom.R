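#' Parameters of the paired brain-hull/endocast phantom
#'
#' The phantom emulates the paired geometry the pipeline assumes: a brain
#' (grooved, flattened ellipsoid) imaged as a bright MRI-like volume, and a
#' cranial shell whose inner surface is the endocast -- the brain surface
#' offset outward by the dura/CSF thickness, with groove imprints attenuated,
#' a fraction of sulci absent, a smoothed superior cap carrying a midline
#' sagittal-sinus ridge, and a known rigid+scale offset between the two
#' "modalities".
#'
#' @param semi_axes ellipsoid semi-axes (mm), adult-human brain scale.
#' @param base_cut flat base: the brain is cut at `z = -base_cut * semi_axes[3]`.
#' @param n_sulci number of carved grooves (max 18, the label vocabulary).
#' @param groove_depth groove depth (mm) on the brain.
#' @param groove_width groove width (mm).
#' @param shell_thickness brain-to-endocast outward offset (mm).
#' @param depth_attenuation in `[0, 1]`: endocast grooves have depth
#'   `groove_depth * (1 - depth_attenuation)`.
#' @param drop_fraction in `[0, 1)`: fraction of sulci absent from the
#'   endocast (`round(drop_fraction * n_sulci)` labels dropped).
#' @param superior_smoothing extra outward offset (mm) of the endocast's
#'   superior cap, emulating the superior-region mismatch.
#' @param sinus_ridge_height height (mm) of the midline sagittal-sinus ridge
#'   on the endocast's superior cap.
#' @param cap_angle polar half-angle (degrees) of the superior cap about +z.
#' @param skull_thickness thickness (mm) of the bony shell in the CT volume.
#' @param modality_transform [similarity_transform()] mapping anatomy (MRI)
#'   world coordinates into the CT frame.
#' @param voxel_size isotropic voxel size (mm); grooves must span at least
#'   two voxels (`voxel_size <= groove_width / 2`).
#' @param noise_sd additive Gaussian intensity noise (MRI units; the CT volume
#'   uses independent noise of the same sd on its own intensity scale).
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   its parameters.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(semi_axes = c(80, 65, 55), base_cut = 0.75,
                           n_sulci = 10, groove_depth = 4, groove_width = 6,
                           shell_thickness = 2, depth_attenuation = 0.4,
                           drop_fraction = 0.2, superior_smoothing = 3,
                           sinus_ridge_height = 2, cap_angle = 35,
                           skull_thickness = 6,
                           modality_transform = similarity_transform(
                             rotation_matrix(z = 5), c(5, -3, 4), 1.02),
                           voxel_size = 2, noise_sd = 4, seed = 1) {
  p <- list(semi_axes = as.numeric(semi_axes), base_cut = base_cut,
            n_sulci = as.integer(n_sulci), groove_depth = groove_depth,
            groove_width = groove_width, shell_thickness = shell_thickness,
            depth_attenuation = depth_attenuation,
            drop_fraction = drop_fraction,
            superior_smoothing = superior_smoothing,
            sinus_ridge_height = sinus_ridge_height, cap_angle = cap_angle,
            skull_thickness = skull_thickness,
            modality_transform = modality_transform,
            voxel_size = voxel_size, noise_sd = noise_sd,
            seed = as.integer(seed))
  stopifnot(length(p$semi_axes) == 3, all(p$semi_axes > 0),
            p$base_cut > 0, p$base_cut <= 1,
            p$n_sulci >= 0, p$n_sulci <= 18,
            p$groove_depth >= 0, p$groove_width > 0,
            p$shell_thickness > 0,
            p$depth_attenuation >= 0, p$depth_attenuation <= 1,
            p$drop_fraction >= 0, p$drop_fraction < 1,
            p$superior_smoothing >= 0, p$sinus_ridge_height >= 0,
            p$cap_angle > 0, p$cap_angle < 90, p$skull_thickness > 0,
            p$voxel_size > 0, p$noise_sd >= 0,
            inherits(p$modality_transform, "similarity_transform"))
  if (p$voxel_size > p$groove_width / 2)
    stop("grooves would be sub-voxel: require voxel_size <= groove_width / 2")
  structure(p, class = "phantom_params")
}

# internal: star-shaped base radius with flat-base clamp, per direction row
phantom_base_radius <- function(u, semi_axes, zb) {
  r <- 1 / sqrt((u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
                  (u[, 3] / semi_axes[3])^2)
  dn <- u[, 3] < 0
  r[dn] <- pmin(r[dn], zb / (-u[dn, 3]))
  r
}

# internal: per-point groove indentation depth.
# paths: list of (points) mouth-level polylines; depths: per-path full depth.
phantom_indent <- function(pts, paths, depths, width) {
  ind <- numeric(nrow(pts))
  hw <- width / 2
  for (i in seq_along(paths)) {
    if (depths[i] <= 0) next
    pp <- paths[[i]]
    n <- nrow(pp)
    d <- cpp_min_dist_segments(pts, pp[-n, , drop = FALSE],
                               pp[-1, , drop = FALSE])
    ind <- pmax(ind, depths[i] * pmax(0, 1 - (d / hw)^2))
  }
  ind
}

# internal: superior-cap weight (1 at the pole, 0 outside cap_angle)
phantom_cap_weight <- function(u, cap_angle) {
  theta <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
  w <- numeric(nrow(u))
  inside <- theta < cap_angle
  w[inside] <- 0.5 * (1 + cos(pi * theta[inside] / cap_angle))
  w
}

# internal: generate the seeded groove-arc catalogue on the direction sphere.
# Arcs are great-circle segments in a polar band, pairwise separated by at
# least 2 * groove_width at the surface.
phantom_groove_arcs <- function(params) {
  n <- params$n_sulci
  if (n == 0) return(list())
  ax <- params$semi_axes
  zb <- params$base_cut * ax[3]
  min_sep <- 2 * params$groove_width
  arcs <- list()
  attempts <- 0
  while (length(arcs) < n && attempts < 2000) {
    attempts <- attempts + 1
    theta <- runif(1, 55, 125) * pi / 180
    phi <- runif(1, 0, 2 * pi)
    cdir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    # random tangent direction at cdir
    a <- rnorm(3)
    a <- a - sum(a * cdir) * cdir
    a <- a / sqrt(sum(a^2))
    half <- runif(1, 22, 40) * pi / 180
    t <- seq(-half, half, length.out = max(2, ceiling(2 * half / 0.03)))
    u <- outer(cos(t), cdir) + outer(sin(t), a)
    # keep arcs off the flat base and the superior cap
    pol <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
    if (any(pol < params$cap_angle + 8) || any(u[, 3] < -0.55)) next
    r <- phantom_base_radius(u, ax, zb)
    pts <- u * r
    ok <- TRUE
    for (prev in arcs) {
      pp <- prev$points
      m <- nrow(pp)
      d <- cpp_min_dist_segments(pts, pp[-m, , drop = FALSE],
                                 pp[-1, , drop = FALSE])
      if (min(d) < min_sep) { ok <- FALSE; break }
    }
    if (ok) arcs <- c(arcs, list(list(dirs = u, points = pts)))
  }
  if (length(arcs) < n)
    stop("could not place ", n, " grooves with the required separation; ",
         "reduce n_sulci or groove_width")
  arcs
}

#' Generate a paired brain/endocast phantom
#'
#' Builds the MRI-like brain volume, the CT-like cranial volume posed under
#' the modality transform, and the exact ground truth: brain and endocast
#' surface meshes, labelled sulcal ground-truth curves on each surface (at
#' groove mid-depth), the dropped labels and the true modality transform.
#' Ground-truth meshes and curves are in the anatomy (MRI) frame; the CT
#' volume lives in the CT frame reached by `modality_transform`.
#' Deterministic given `params$seed`.
#'
#' @param params a [phantom_params()].
#' @return list with elements `mri` ([volume_image()]), `ct`
#'   ([volume_image()]) and `truth` (class `phantom_truth`: `brain_mesh`,
#'   `endocast_mesh`, `brain_curves`, `endocast_curves`, `dropped_labels`,
#'   `modality_transform`, `params`).
#' @export
make_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  local_seed(params$seed)
  ax <- params$semi_axes
  zb <- params$base_cut * ax[3]
  vs <- params$voxel_size
  shell <- params$shell_thickness
  skull <- params$skull_thickness

  arcs <- phantom_groove_arcs(params)
  vocab <- sulcus_vocabulary()
  labels <- vocab[seq_len(params$n_sulci)]
  sides <- vapply(arcs, function(a) {
    mx <- mean(a$points[, 1])
    if (mx < -5) "left" else if (mx > 5) "right" else "midline"
  }, "")
  n_drop <- round(params$drop_fraction * params$n_sulci)
  dropped <- if (n_drop > 0) sort(sample(labels, n_drop)) else character(0)
  kept <- !(labels %in% dropped)
  paths <- lapply(arcs, function(a) a$points)
  att_depth <- params$groove_depth * (1 - params$depth_attenuation)

  brain_radius <- function(u) {
    r <- phantom_base_radius(u, ax, zb)
    if (length(paths))
      r <- r - phantom_indent(u * r, paths,
                              rep(params$groove_depth, length(paths)),
                              params$groove_width)
    r
  }
  endo_radius <- function(u) {
    r0 <- phantom_base_radius(u, ax, zb)
    r <- r0 + shell
    if (length(paths) && any(kept) && att_depth > 0)
      r <- r - phantom_indent(u * r0, paths[kept],
                              rep(att_depth, sum(kept)),
                              params$groove_width)
    w <- phantom_cap_weight(u, params$cap_angle)
    r <- r + params$superior_smoothing * w
    if (params$sinus_ridge_height > 0) {
      xs <- u[, 1] * (r0 + shell)
      r <- r + params$sinus_ridge_height * exp(-(xs / 3)^2 / 2) * w
    }
    r
  }

  # --- truth meshes (icosphere sampling of the radius functions) ---
  sph <- icosphere(5)
  u <- sph$vertices
  brain_mesh <- triangle_mesh(u * brain_radius(u), sph$faces)
  ue <- sph$vertices
  endocast_mesh <- triangle_mesh(ue * endo_radius(ue), sph$faces)

  # --- truth curves at groove mid-depth ---
  mk_curves <- function(offset, depth, keep, source) {
    cs <- list()
    for (i in seq_along(arcs)) {
      if (!keep[i]) next
      a <- arcs[[i]]
      r <- phantom_base_radius(a$dirs, ax, zb) + offset - depth / 2
      cs <- c(cs, list(labeled_curve(a$dirs * r, label = labels[i],
                                     side = sides[i])))
    }
    curve_set(cs, source = source)
  }
  brain_curves <- mk_curves(0, params$groove_depth, rep(TRUE, length(arcs)),
                            "brain-hull")
  endocast_curves <- mk_curves(shell, att_depth, kept, "endocast")

  # --- MRI volume (anatomy frame) ---
  pad <- 4 * vs
  ext <- max(ax) + pad
  nv <- ceiling(2 * ext / vs) + 1
  origin <- -(nv - 1) / 2 * vs
  mri <- volume_image(array(0, rep(nv, 3)), rep(vs, 3), rep(origin, 3))
  ctr <- voxel_centers(mri)
  rr <- sqrt(rowSums(ctr^2))
  uu <- ctr / pmax(rr, 1e-12)
  rb <- phantom_base_radius(uu, ax, zb)
  inside <- rr <= rb & ctr[, 3] >= -zb
  # grooves only matter near the surface
  band <- inside & rr > rb - params$groove_depth - vs
  if (length(paths) && any(band)) {
    ind <- phantom_indent(uu[band, , drop = FALSE] * rb[band], paths,
                          rep(params$groove_depth, length(paths)),
                          params$groove_width)
    inside[band] <- rr[band] <= rb[band] - ind
  }
  vals <- ifelse(inside, 100, 10) + rnorm(length(inside), sd = params$noise_sd)
  mri$values <- array(vals, dim(mri$values))

  # --- CT volume (CT frame, anatomy pulled back through the transform) ---
  tf <- params$modality_transform
  ext_ct <- max(ax) + shell + skull + pad
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * ext_ct
  cc <- apply_transform(tf, corners)
  lo <- floor(apply(cc, 2, min) / vs) * vs
  hi <- ceiling(apply(cc, 2, max) / vs) * vs
  nct <- round((hi - lo) / vs) + 1
  ct <- volume_image(array(0, nct), rep(vs, 3), lo)
  pts <- apply_transform(invert_transform(tf), voxel_centers(ct))
  rr <- sqrt(rowSums(pts^2))
  uu <- pts / pmax(rr, 1e-12)
  r0 <- phantom_base_radius(uu, ax, zb)
  # endocast cavity
  re <- r0 + shell
  w <- phantom_cap_weight(uu, params$cap_angle)
  re <- re + params$superior_smoothing * w
  if (params$sinus_ridge_height > 0)
    re <- re + params$sinus_ridge_height *
      exp(-((uu[, 1] * (r0 + shell)) / 3)^2 / 2) * w
  in_endo <- rr <= re & pts[, 3] >= -(zb + shell)
  band <- in_endo & rr > re - att_depth - vs
  if (length(paths) && any(kept) && att_depth > 0 && any(band)) {
    ind <- phantom_indent(uu[band, , drop = FALSE] * r0[band], paths[kept],
                          rep(att_depth, sum(kept)), params$groove_width)
    in_endo[band] <- rr[band] <= re[band] - ind
  }
  in_outer <- rr <= r0 + shell + skull + params$superior_smoothing * w &
    pts[, 3] >= -(zb + shell + skull)
  vals <- numeric(length(rr))
  vals[in_outer & !in_endo] <- 1000
  vals[in_endo] <- 40
  vals <- vals + rnorm(length(vals), sd = params$noise_sd)
  ct$values <- array(vals, dim(ct$values))

  truth <- structure(list(brain_mesh = brain_mesh,
                          endocast_mesh = endocast_mesh,
                          brain_curves = brain_curves,
                          endocast_curves = endocast_curves,
                          dropped_labels = dropped,
                          modality_transform = tf,
                          params = params),
                     class = "phantom_truth")
  list(mri = mri, ct = ct, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", length(x$brain_curves), "brain curves,",
      length(x$endocast_curves), "endocast curves,",
      length(x$dropped_labels), "dropped labels\n")
  invisible(x)
}

#' Carve a groove into a volume along a surface path
#'
#' Erodes the bright foreground along a tube of the given width and depth
#' around a path lying on (or near) the foreground surface. The groove is
#' swept inward from the path toward the foreground centroid. Voxels outside
#' the tube are unchanged; `depth = 0` is the identity. Carving two paths
#' with disjoint supports commutes.
#'
#' @param volume a [volume_image()] with a bright foreground.
#' @param path n x 3 matrix of path points (mm) on the foreground surface.
#' @param depth groove depth (mm).
#' @param width groove width (mm).
#' @param isovalue foreground threshold; defaults to the intensity midrange.
#' @param background value carved voxels are set to; defaults to the volume
#'   minimum.
#' @return the carved [volume_image()].
#' @export
carve_groove <- function(volume, path, depth, width, isovalue = NULL,
                         background = NULL) {
  path <- as_points(path)
  stopifnot(depth >= 0, width > 0)
  d <- dim(volume$values)
  lo <- volume$origin
  hi <- volume$origin + (d - 1) * volume$spacing
  if (any(path < rep(lo, each = nrow(path))) ||
      any(path > rep(hi, each = nrow(path))))
    stop("path lies outside the volume bounds")
  if (depth == 0) return(volume)
  if (is.null(isovalue)) isovalue <- mean(range(volume$values))
  if (is.null(background)) background <- min(volume$values)
  fg <- which(volume$values >= isovalue, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("no foreground to carve")
  centroid <- colMeans(sweep(sweep(fg - 1, 2, volume$spacing, "*"), 2,
                             volume$origin, "+"))
  # sweep the path inward toward the centroid to form the groove sheet
  step <- min(volume$spacing) / 2
  ts <- seq(step, depth, by = step)
  inward <- sweep(-path, 2, -centroid, "-")  # centroid - path
  inward <- inward / pmax(sqrt(rowSums(inward^2)), 1e-12)
  sheet <- do.call(rbind, lapply(ts, function(t) path + t * inward))
  sheet <- rbind(path, sheet)
  # candidate voxels: bounding box of the sheet, expanded by width
  blo <- pmax(apply(sheet, 2, min) - width, lo)
  bhi <- pmin(apply(sheet, 2, max) + width, hi)
  ilo <- pmax(1, floor((blo - lo) / volume$spacing) + 1)
  ihi <- pmin(d, ceiling((bhi - lo) / volume$spacing) + 1)
  g <- as.matrix(expand.grid(x = ilo[1]:ihi[1], y = ilo[2]:ihi[2],
                             z = ilo[3]:ihi[3]))
  w <- sweep(sweep(g - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  dist <- cpp_min_dist_segments(w, sheet, sheet)  # point cloud distances
  carve <- dist <= width / 2
  if (any(carve)) {
    idx <- g[carve, , drop = FALSE]
    volume$values[idx] <- background
  }
  volume
}
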