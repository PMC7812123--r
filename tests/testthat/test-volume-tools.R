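make_noise_volume <- function(n = 40, seed = 1) {
  set.seed(seed)
  volume_image(array(rnorm(n^3), rep(n, 3)), c(1, 1, 1),
               rep(-(n - 1) / 2, 3))
}

test_that("NMI hits its analytic anchors", {
  v <- make_noise_volume()
  expect_equal(nmi(v, v), 2)
  const <- volume_image(array(7, dim(v$values)), v$spacing, v$origin)
  expect_equal(nmi(v, const), 1)
  # independently shuffled copy: NMI approaches 1 (bound checked at 64^3)
  set.seed(2)
  big <- make_noise_volume(64, seed = 3)
  shuf <- volume_image(array(sample(big$values), dim(big$values)),
                       big$spacing, big$origin)
  expect_lt(nmi(big, shuf), 1.1)
  expect_gt(nmi(big, shuf), 1)
})

test_that("NMI is symmetric and invariant to monotone intensity remapping", {
  v <- make_noise_volume(32, seed = 4)
  set.seed(5)
  w <- volume_image(v$values + array(rnorm(32^3, sd = 0.5), dim(v$values)),
                    v$spacing, v$origin)
  expect_equal(nmi(v, w), nmi(w, v), tolerance = 1e-6)
  # strictly monotone remap that preserves bin occupancy boundaries:
  # affine maps keep linear binning identical
  w2 <- volume_image(3 * w$values + 11, w$spacing, w$origin)
  expect_equal(nmi(v, w2), nmi(v, w), tolerance = 1e-12)
})

test_that("resample_volume is exact on identity and integer shifts", {
  v <- make_noise_volume(24, seed = 6)
  r <- resample_volume(v, similarity_transform(), v)
  expect_equal(r$values, v$values)
  tr <- similarity_transform(translation = c(3, 0, 0))  # 3 voxels at 1 mm
  r2 <- resample_volume(v, tr, v, background = 0)
  expect_equal(r2$values[4:24, , ], v$values[1:21, , ])
  expect_true(all(r2$values[1:3, , ] == 0))
})

test_that("resample round trip loses less than 1% of the dynamic range", {
  v <- make_noise_volume(32, seed = 7)
  # smooth field: interpolation loss is meaningful, not noise-dominated
  ctr <- voxel_centers(v)
  v$values <- array(sin(ctr[, 1] / 4) + cos(ctr[, 2] / 5) +
                      sin(ctr[, 3] / 6), dim(v$values))
  tf <- similarity_transform(rotation_matrix(z = 7), c(1.3, -0.7, 0.4))
  fwd <- resample_volume(v, tf, v, background = NA)
  back <- resample_volume(fwd, invert_transform(tf), v, background = NA)
  core <- 6:27
  err <- abs(back$values[core, core, core] - v$values[core, core, core])
  rng <- diff(range(v$values))
  expect_lt(mean(err, na.rm = TRUE), 0.01 * rng)
})

test_that("NIfTI round trip preserves grid and values", {
  v <- make_noise_volume(16, seed = 8)
  v$spacing <- c(0.5, 0.75, 1.25)
  v$origin <- c(-10, 3, 2.5)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$values, v$values)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("NMI rigid registration recovers identity and improves NMI", {
  ph <- phantom_fixture()
  est <- register_rigid_nmi(ph$ct, ph$ct, grid_mm = 0)
  expect_lt(sqrt(sum(est$translation^2)), 0.1)
  expect_lt(rotation_angle_deg(est$rotation), 0.1)
  expect_gte(attr(est, "nmi"), attr(est, "nmi_init"))
})

test_that("empty overlap raises an error", {
  v <- make_noise_volume(16, seed = 9)
  far <- similarity_transform(translation = c(1000, 0, 0))
  expect_error(nmi(v, v, far), "overlap")
})
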