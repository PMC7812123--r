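# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default-condition phantom (cached)
phantom_fixture <- function(seed = 3) {
  key <- paste0("phantom_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_phantom(phantom_params(seed = seed))
  .fixture_env[[key]]
}

# small, fast phantom for pipeline-level tests
small_phantom_config <- function(seed = 5, ...) {
  pipeline_config(
    seed = seed,
    phantom = list(semi_axes = c(55, 46, 40), n_sulci = 6,
                   superior_smoothing = 0, sinus_ridge_height = 0,
                   depth_attenuation = 0, drop_fraction = 0),
    segment = list(target_faces = 10000),
    register = list(mesh_faces = 1200, n_control_points = 300,
                    max_iters = 15),
    verbosity = 0,
    ...)
}

# closed cylinder with flat caps (axis z), for analytic curvature checks
cylinder_mesh <- function(radius = 5, half_height = 20, n_theta = 72,
                          n_z = 41) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(-half_height, half_height, length.out = n_z)
  V <- cbind(rep(radius * cos(th), n_z), rep(radius * sin(th), n_z),
             rep(zs, each = n_theta))
  idx <- function(i, j) (j - 1) * n_theta + ((i - 1) %% n_theta) + 1
  F <- matrix(0L, 0, 3)
  for (j in 1:(n_z - 1)) {
    i <- 1:n_theta
    F <- rbind(F,
               cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
               cbind(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  V <- rbind(V, c(0, 0, -half_height), c(0, 0, half_height))
  bot <- nrow(V) - 1L
  top <- nrow(V)
  i <- 1:n_theta
  F <- rbind(F, cbind(idx(i + 1, 1), idx(i, 1), bot),
             cbind(idx(i, n_z), idx(i + 1, n_z), top))
  triangle_mesh(V, F)
}

# binary ball volume on an isotropic grid centered at the origin
ball_volume <- function(radius = 30, voxel = 2, pad = 4) {
  n <- ceiling(2 * (radius + pad * voxel) / voxel) + 1
  org <- -(n - 1) / 2 * voxel
  vol <- volume_image(array(0, rep(n, 3)), rep(voxel, 3), rep(org, 3))
  ctr <- voxel_centers(vol)
  vol$values <- array(as.numeric(sqrt(rowSums(ctr^2)) <= radius),
                      dim(vol$values))
  vol
}

# random small labelled curve sets for matching-oracle tests
random_curve_set <- function(n_curves, labels, source = "unknown") {
  cs <- lapply(seq_len(n_curves), function(i) {
    npt <- sample(2:6, 1)
    start <- runif(3, -30, 30)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pts <- t(sapply(seq_len(npt) - 1, function(k)
      start + k * 4 * dir + rnorm(3, sd = 0.5)))
    labeled_curve(pts, label = sample(labels, 1))
  })
  curve_set(cs, source = source)
}

# brute-force oracle for the matching rule: mean over endocast curve points of
# the min distance to densely resampled same-label brain points; matched iff
# strictly below tau
oracle_match <- function(endo, brain, tau = 10) {
  densify <- function(p) {
    out <- NULL
    for (i in 1:(nrow(p) - 1)) {
      t <- seq(0, 1, length.out = 200)
      out <- rbind(out, outer(1 - t, p[i, ]) + outer(t, p[i + 1, ]))
    }
    out
  }
  dists <- vapply(endo$curves, function(ec) {
    pool <- lapply(Filter(function(b) b$label == ec$label, brain$curves),
                   function(b) densify(b$points))
    if (length(pool) == 0) return(NA_real_)
    pool <- do.call(rbind, pool)
    mean(apply(ec$points, 1, function(q)
      min(sqrt(rowSums(sweep(pool, 2, q)^2)))))
  }, 0)
  matched <- !is.na(dists) & dists < tau
  list(dists = dists, nc_eb = sum(matched), ns_eb = sum(!matched))
}
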