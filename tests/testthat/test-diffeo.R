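test_that("align_rigid_scale recovers identity and a known similarity", {
  src <- icosphere(3, radius = 30)
  src$vertices <- src$vertices * cbind(rep(1.3, nrow(src$vertices)), 1, 0.8)
  # target = source
  est0 <- align_rigid_scale(src, src)
  expect_lt(abs(est0$scale - 1), 1e-6)
  expect_lt(sqrt(sum(est0$translation^2)), 1e-4)
  # known 1.2 scale + 10 degree rotation
  tf <- similarity_transform(rotation_matrix(z = 10), c(5, 2, -3), 1.2)
  tgt <- triangle_mesh(apply_transform(tf, src$vertices), src$faces)
  est <- align_rigid_scale(src, tgt)
  expect_lt(abs(est$scale - 1.2), 0.01)
  err <- compose_transform(invert_transform(tf), est)
  expect_lt(rotation_angle_deg(err$rotation), 0.5)
  # monotone contract on an arbitrary pair
  a <- icosphere(2, radius = 12)
  b <- icosphere(2, c(4, 1, -2), 15)
  estab <- align_rigid_scale(a, b)
  tr <- attr(estab, "trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("degenerate flat sources are rejected", {
  flat <- triangle_mesh(cbind(runif(12), runif(12), 0),
                        matrix(c(1, 2, 3, 2, 3, 4, 4, 5, 6, 7, 8, 9), 4, 3,
                               byrow = TRUE))
  tgt <- icosphere(2, radius = 5)
  expect_error(align_rigid_scale(flat, tgt), "degenerate")
})

test_that("registering a mesh to itself keeps zero momenta optimal", {
  s <- icosphere(3, radius = 25)
  res <- register_diffeo(s, s, n_control_points = 200, max_iters = 10)
  expect_lte(res$final_data_term, 1e-8)
  expect_true(all(res$model$momenta == 0))
})

test_that("sphere-to-translated-sphere registration shrinks the varifold gap", {
  s1 <- icosphere(3, radius = 30)
  s2 <- icosphere(3, c(5, 0, 0), 30)
  d0 <- varifold_distance(s1, s2, 5)
  res <- register_diffeo(s1, s2, n_control_points = 500, max_iters = 60,
                         seed = 1)
  d1 <- varifold_distance(res$deformed_source, s2, 5)
  expect_lte(d1 / d0, 0.10)
  # energy trace non-increasing, diffeomorphic at returned settings
  expect_true(all(diff(res$energy_trace) <= 1e-12))
  n0 <- face_normals(s1)
  n1 <- face_normals(res$deformed_source)
  expect_true(all(rowSums(n0 * n1) > 0))  # no face inversions
})

test_that("transport is the identity at zero momenta and consistent with the flow", {
  set.seed(16)
  C <- matrix(rnorm(30, sd = 10), 10, 3)
  model0 <- deformation_model(C, matrix(0, 10, 3), kernel_width = 15)
  pts <- matrix(rnorm(60, sd = 20), 20, 3)
  expect_lt(max(abs(transport_points(model0, pts) - pts)), 1e-9)
  # consistency with deformed_source
  s1 <- icosphere(2, radius = 20)
  s2 <- icosphere(2, c(3, 0, 0), 20)
  res <- register_diffeo(s1, s2, n_control_points = 150, max_iters = 20)
  tp <- transport_points(res$model, s1$vertices)
  expect_lt(max(abs(tp - res$deformed_source$vertices)), 1e-6)
})

test_that("transported curves keep labels and follow the deformed surface", {
  s1 <- icosphere(3, radius = 20)
  s2 <- icosphere(3, c(4, 0, 0), 20)
  res <- register_diffeo(s1, s2, n_control_points = 300, max_iters = 40,
                         data_kernel_width = 5)
  eq <- s1$vertices[abs(s1$vertices[, 3]) < 2, ]
  eq <- eq[order(atan2(eq[, 2], eq[, 1])), ][1:12, ]
  cs <- curve_set(list(labeled_curve(eq, "central", "left")), "brain-hull")
  out <- transport_curves(res$model, cs)
  expect_identical(out$curves[[1]]$label, "central")
  expect_identical(out$curves[[1]]$side, "left")
  d <- closest_point_mesh(res$deformed_source, out$curves[[1]]$points)$distance
  expect_true(all(d <= 2 * 5))  # within 2x the data kernel width
})

test_that("cycle consistency: registering back returns near the source", {
  s1 <- icosphere(2, radius = 20)
  s2 <- icosphere(2, c(4, 0, 0), 20)
  fwd <- register_diffeo(s1, s2, n_control_points = 200, max_iters = 30)
  bwd <- register_diffeo(fwd$deformed_source, s1, n_control_points = 200,
                         max_iters = 30)
  cyc <- max(sqrt(rowSums((bwd$deformed_source$vertices -
                             s1$vertices)^2)))
  expect_lt(cyc, 1.0)  # pinned tolerance on this fixture
})
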