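test_that("parameter invariants are enforced", {
  expect_error(phantom_params(voxel_size = 4, groove_width = 6), "sub-voxel")
  expect_error(phantom_params(drop_fraction = 1))
  expect_error(phantom_params(depth_attenuation = 1.2))
  expect_error(phantom_params(shell_thickness = 0))
})

test_that("dropped-label bookkeeping follows the drop fraction", {
  ph <- make_phantom(phantom_params(n_sulci = 12, drop_fraction = 0.25,
                                    seed = 21))
  expect_length(ph$truth$dropped_labels, 3)  # round(0.25 * 12)
  endo_labels <- curve_labels(ph$truth$endocast_curves)
  expect_length(endo_labels, 9)
  brain_labels <- curve_labels(ph$truth$brain_curves)
  # every endocast label occurs among brain labels
  expect_true(all(endo_labels %in% brain_labels))
  expect_true(all(ph$truth$dropped_labels %in% brain_labels))
  expect_false(any(ph$truth$dropped_labels %in% endo_labels))
})

test_that("the endocast truth mesh sits one shell thickness off the brain", {
  ph <- phantom_fixture()
  em <- ph$truth$endocast_mesh
  u <- em$vertices / sqrt(rowSums(em$vertices^2))
  pol <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
  sel <- pol > 50 & pol < 120
  mind <- rep(Inf, nrow(em$vertices))
  for (cv in ph$truth$brain_curves$curves)
    mind <- pmin(mind, dist_to_polyline(em$vertices, cv))
  sel <- sel & mind > 8  # outside groove and superior regions
  d <- closest_point_mesh(ph$truth$brain_mesh, em$vertices[sel, ])$distance
  expect_lt(abs(mean(d) - 2), 0.25)
})

test_that("phantoms are bit-identical for the same seed and differ across seeds", {
  p <- phantom_params(seed = 7, n_sulci = 4)
  a <- make_phantom(p)
  b <- make_phantom(p)
  expect_identical(a$mri$values, b$mri$values)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth$brain_curves, b$truth$brain_curves)
  c3 <- make_phantom(phantom_params(seed = 8, n_sulci = 4))
  expect_false(identical(a$mri$values, c3$mri$values))
})

test_that("ground-truth labels are a bijection onto carved grooves", {
  ph <- phantom_fixture()
  labs <- vapply(ph$truth$brain_curves$curves, function(cv) cv$label, "")
  expect_identical(sort(labs), sort(unique(labs)))
  expect_length(labs, ph$truth$params$n_sulci)
  # each truth curve sits in a groove: local surface depression of the mask
  iso <- mean(range(ph$mri$values))
  for (cv in ph$truth$brain_curves$curves[1:3]) {
    mid <- cv$points[ceiling(nrow(cv$points) / 2), , drop = FALSE]
    expect_lt(sample_volume(ph$mri, mid, clamp = TRUE), iso)  # carved out
    inward <- mid * (1 - (ph$truth$params$groove_depth + 2) /
                       sqrt(sum(mid^2)))
    expect_gt(sample_volume(ph$mri, inward, clamp = TRUE), iso)
  }
})

test_that("carve_groove is the identity at depth 0 and commutes for disjoint paths", {
  vol <- ball_volume(radius = 20, voxel = 2)
  th <- seq(-0.6, 0.6, length.out = 40)
  p1 <- cbind(20 * cos(th), 0, 20 * sin(th))
  p2 <- cbind(0, 20 * cos(th), 20 * sin(th))
  expect_identical(carve_groove(vol, p1, 0, 6)$values, vol$values)
  a <- carve_groove(carve_groove(vol, p1, 4, 6), p2, 4, 6)
  b <- carve_groove(carve_groove(vol, p2, 4, 6), p1, 4, 6)
  expect_identical(a$values, b$values)
  expect_error(carve_groove(vol, p1 + 500, 4, 6), "bounds")
})

test_that("carving a groove increases the exposed surface area", {
  vol <- ball_volume(radius = 20, voxel = 2)
  exposed_area <- function(v) {
    m <- v$values >= 0.5
    d <- dim(m)
    faces <- 0
    shift_diff <- function(a, b) sum(a & !b) + sum(b & !a)
    faces <- faces + shift_diff(m[-d[1], , ], m[-1, , ])
    faces <- faces + shift_diff(m[, -d[2], ], m[, -1, ])
    faces <- faces + shift_diff(m[, , -d[3]], m[, , -1])
    faces * prod(v$spacing[1:2])
  }
  th <- seq(-0.6, 0.6, length.out = 40)
  path <- cbind(20 * cos(th), 0, 20 * sin(th))
  carved <- carve_groove(vol, path, 5, 6)
  expect_gt(exposed_area(carved), exposed_area(vol))
})

test_that("deeper endocast attenuation removes detectable groove relief", {
  # geometric check on the truth meshes: with attenuation 1 the endocast is
  # smooth (kmin never strongly negative), with attenuation 0 grooves remain
  p0 <- phantom_params(seed = 9, n_sulci = 6, depth_attenuation = 0,
                       superior_smoothing = 0, sinus_ridge_height = 0,
                       drop_fraction = 0)
  p1 <- phantom_params(seed = 9, n_sulci = 6, depth_attenuation = 1,
                       superior_smoothing = 0, sinus_ridge_height = 0,
                       drop_fraction = 0)
  m0 <- make_phantom(p0)$truth$endocast_mesh
  m1 <- make_phantom(p1)$truth$endocast_mesh
  f0 <- estimate_curvature(resample_mesh(m0, 8000))
  f1 <- estimate_curvature(resample_mesh(m1, 8000))
  expect_lt(quantile(f0$kmin, 0.001), -0.2)   # deep concave grooves
  expect_gt(quantile(f1$kmin, 0.001), -0.05)  # vanished
})
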