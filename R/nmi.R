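#' Normalized mutual information between two volumes
#'
#' Computes the overlap-normalized mutual information
#' \deqn{NMI = (H(A) + H(B)) / H(A, B)}
#' (Studholme variant) over the voxels of `fixed` whose pull-back through
#' `transform` falls inside `moving`. Intensities are min-max scaled over the
#' overlap region and binned linearly into `n_bins` bins per channel.
#' NMI lies in (1, 2]: 2 for identical images, 1 for independent ones.
#'
#' @param fixed,moving [volume_image()] objects.
#' @param transform a [similarity_transform()] mapping `moving` world
#'   coordinates into the `fixed` frame.
#' @param n_bins histogram bins per channel (>= 2).
#' @param stride sample every `stride`-th voxel per axis of the fixed grid
#'   (1 = all voxels).
#' @return NMI value (unitless).
#' @export
nmi <- function(fixed, moving, transform = similarity_transform(),
                n_bins = 64, stride = 1L) {
  stopifnot(n_bins >= 2)
  samp <- nmi_samples(fixed, stride)
  nmi_at(samp, moving, transform, n_bins)
}

# internal: precompute fixed-image sample points/values for repeated NMI calls
nmi_samples <- function(fixed, stride = 1L) {
  d <- dim(fixed$values)
  ix <- seq(1, d[1], by = stride)
  iy <- seq(1, d[2], by = stride)
  iz <- seq(1, d[3], by = stride)
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  pts <- sweep(sweep(g - 1, 2, fixed$spacing, "*"), 2, fixed$origin, "+")
  vals <- fixed$values[g]
  list(points = pts, values = vals)
}

# internal: NMI given precomputed fixed samples
nmi_at <- function(samples, moving, transform, n_bins) {
  src <- apply_transform(invert_transform(transform), samples$points)
  b <- sample_volume(moving, src)
  keep <- !is.na(b)
  if (!any(keep)) stop("empty overlap region between the two volumes")
  a <- samples$values[keep]
  b <- b[keep]
  bin <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    i <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
    pmin.int(i, n_bins)
  }
  ai <- bin(a)
  bi <- bin(b)
  joint <- tabulate(ai + n_bins * (bi - 1L), nbins = n_bins * n_bins)
  p <- joint / sum(joint)
  pm <- matrix(p, n_bins, n_bins)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  ha <- ent(rowSums(pm))
  hb <- ent(colSums(pm))
  hab <- ent(p)
  if (hab == 0) return(2)  # identical constant images
  (ha + hb) / hab
}

# internal: separable radius-1 box smoothing, `passes` times per axis.
# Applied to both volumes before computing the registration metric: it turns
# near-binary intensities into smooth ramps, which removes spurious local
# optima of the sampled NMI without moving its maximizer.
smooth_volume_box <- function(volume, passes = 2) {
  a <- volume$values
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- dim(a)[ax]
      im <- c(1, seq_len(n - 1))
      ip <- c(seq_len(n - 1) + 1, n)
      a <- switch(ax,
                  (a[im, , , drop = FALSE] + a + a[ip, , , drop = FALSE]) / 3,
                  (a[, im, , drop = FALSE] + a + a[, ip, , drop = FALSE]) / 3,
                  (a[, , im, drop = FALSE] + a + a[, , ip, drop = FALSE]) / 3)
    }
  }
  volume$values <- a
  volume
}

#' Rigid registration of two volumes by NMI maximization
#'
#' Finds the rigid transform (scale fixed at 1) mapping `moving` world
#' coordinates into the `fixed` frame that maximizes normalized mutual
#' information. Both volumes are box-smoothed for the metric (the returned
#' transform applies to the originals). A coarse multi-start grid over
#' translations, then over rotations, is followed by repeated Nelder-Mead
#' refinement over the 6 rigid degrees of freedom (translation in mm,
#' rotations in degrees about the fixed-image center). The capture range at
#' the default settings is roughly +-8 mm and +-9 degrees.
#'
#' @param fixed,moving [volume_image()] objects.
#' @param init initial [similarity_transform()] (scale must be 1).
#' @param n_bins histogram bins for [nmi()].
#' @param grid_mm coarse translation search: offsets `-grid_mm, 0, +grid_mm`
#'   per axis around `init` (set 0 to skip both coarse grids).
#' @param grid_deg coarse rotation search offsets, analogous to `grid_mm`.
#' @param max_iter maximum Nelder-Mead iterations per restart.
#' @param max_samples cap on fixed-grid sample count (sets the stride).
#' @param smoothing_passes box-smoothing passes applied to both volumes for
#'   the metric (0 disables).
#' @return the optimized [similarity_transform()], with attributes `nmi`
#'   (at the solution, on the smoothed volumes), `nmi_init`, and `converged`
#'   (`FALSE` when the optimizer failed to improve on `init`, in which case
#'   `init` is returned).
#' @export
register_rigid_nmi <- function(fixed, moving, init = similarity_transform(),
                               n_bins = 32, grid_mm = 4, grid_deg = 6,
                               max_iter = 600, max_samples = 150000,
                               smoothing_passes = 2) {
  if (abs(init$scale - 1) > 1e-12)
    stop("volume registration is rigid: init must have scale 1")
  if (smoothing_passes > 0) {
    fixed <- smooth_volume_box(fixed, smoothing_passes)
    moving <- smooth_volume_box(moving, smoothing_passes)
  }
  d <- dim(fixed$values)
  stride <- max(1L, ceiling((prod(d) / max_samples)^(1 / 3)))
  samp <- nmi_samples(fixed, stride)
  center <- fixed$origin + (d - 1) / 2 * fixed$spacing

  par_to_transform <- function(p) {
    R <- rotation_matrix(p[4], p[5], p[6])
    # rotation about the fixed-image center, then translation
    tr <- similarity_transform(rotation = R,
                               translation = center - as.vector(R %*% center) +
                                 p[1:3])
    compose_transform(tr, init)
  }
  obj <- function(p) -nmi_at(samp, moving, par_to_transform(p), n_bins)

  p <- rep(0, 6)
  val <- obj(p)
  if (grid_mm > 0) {
    offs <- c(-grid_mm, 0, grid_mm)
    tg <- as.matrix(expand.grid(offs, offs, offs))
    vt <- apply(tg, 1, function(t) obj(c(t, 0, 0, 0)))
    bt <- tg[which.min(vt), ]
    ro <- c(-grid_deg, 0, grid_deg)
    rg <- as.matrix(expand.grid(ro, ro, ro))
    vr <- apply(rg, 1, function(r) obj(c(bt, r)))
    p <- c(bt, rg[which.min(vr), ])
    val <- min(vr)
  }
  for (restart in 1:8) {
    fit <- optim(p, obj, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = 1e-9))
    improved <- val - fit$value
    if (fit$value < val) {
      val <- fit$value
      p <- fit$par
    }
    if (improved < 1e-7) break
  }
  nmi_init <- -obj(rep(0, 6))
  nmi_final <- -val
  if (nmi_final >= nmi_init) {
    out <- par_to_transform(p)
    converged <- TRUE
  } else {
    out <- init
    nmi_final <- nmi_init
    converged <- FALSE
    warning("NMI optimization did not improve on the initial transform")
  }
  attr(out, "nmi") <- nmi_final
  attr(out, "nmi_init") <- nmi_init
  attr(out, "converged") <- converged
  out
}
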