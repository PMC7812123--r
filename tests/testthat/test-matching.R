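seg_curve <- function(x0, y0, label = "a", n = 11, len = 20) {
  labeled_curve(cbind(seq(x0, x0 + len, length.out = n), y0, 0), label)
}

test_that("curve_distance matches its closed-form anchors", {
  a <- seg_curve(0, 0, "central")
  expect_equal(curve_distance(a, curve_set(list(a))), 0)
  b <- seg_curve(0, 3, "central")  # 3 mm perpendicular translate
  expect_equal(curve_distance(b, curve_set(list(a))), 3)
  # endocast curve sampled at points 2 mm and 4 mm away -> mean 3
  e <- labeled_curve(rbind(c(5, 2, 0), c(15, 4, 0)), "central")
  expect_equal(curve_distance(e, curve_set(list(a))), 3)
  # absent label -> NA
  f <- seg_curve(0, 1, "lunate")
  expect_true(is.na(curve_distance(f, curve_set(list(a)))))
})

test_that("curve_distance is directional (endocast to brain)", {
  short <- labeled_curve(cbind(seq(0, 5, length.out = 5), 2, 0), "a")
  long <- labeled_curve(cbind(seq(-30, 30, length.out = 30), 0, 0), "a")
  d_short_to_long <- curve_distance(short, curve_set(list(long)))
  d_long_to_short <- curve_distance(long, curve_set(list(short)))
  expect_equal(d_short_to_long, 2)
  expect_gt(d_long_to_short, d_short_to_long)
})

test_that("the matching criterion is strict at tau", {
  a <- seg_curve(0, 0, "central")
  exact <- seg_curve(0, 10, "central")  # mean distance exactly 10.0
  rep1 <- match_curves(curve_set(list(exact)), curve_set(list(a)), tau = 10)
  expect_identical(rep1$NC_EB, 0L)
  expect_identical(rep1$NS_EB, 1L)
  just_under <- seg_curve(0, 10 - 1e-9, "central")
  rep2 <- match_curves(curve_set(list(just_under)), curve_set(list(a)),
                       tau = 10)
  expect_identical(rep2$NC_EB, 1L)
})

test_that("identical curve sets match completely", {
  set.seed(17)
  cs <- random_curve_set(6, sulcus_vocabulary()[1:4])
  rep <- match_curves(cs, cs)
  expect_identical(rep$NC_EB, rep$TC_E)
  expect_identical(rep$NS_EB, 0L)
  expect_true(all(rep$per_curve$mean_distance == 0))
})

test_that("match counts equal the exhaustive brute-force oracle", {
  set.seed(18)
  for (trial in 1:100) {
    labels <- sulcus_vocabulary()[1:sample(2:5, 1)]
    endo <- random_curve_set(sample(1:6, 1), labels)
    brain <- random_curve_set(sample(1:6, 1), labels)
    got <- suppressWarnings(match_curves(endo, brain, tau = 10))
    want <- oracle_match(endo, brain, tau = 10)
    expect_identical(got$NC_EB, as.integer(want$nc_eb))
    expect_identical(got$NS_EB, as.integer(want$ns_eb))
    ok <- !is.na(want$dists)
    expect_equal(got$per_curve$mean_distance[ok], want$dists[ok],
                 tolerance = 1e-3)
  }
})

test_that("matching is invariant to curve order and brain fragmentation", {
  set.seed(19)
  endo <- random_curve_set(5, c("central", "lunate"))
  brain <- random_curve_set(4, c("central", "lunate"))
  r1 <- suppressWarnings(match_curves(endo, brain))
  perm <- sample(length(brain$curves))
  r2 <- suppressWarnings(match_curves(endo, curve_set(brain$curves[perm])))
  expect_identical(r1$NC_EB, r2$NC_EB)
  expect_equal(r1$per_curve$mean_distance, r2$per_curve$mean_distance)
  # split each brain curve into two fragments at an interior vertex
  frags <- unlist(lapply(brain$curves, function(cv) {
    n <- nrow(cv$points)
    if (n < 4) return(list(cv))
    k <- ceiling(n / 2)
    list(labeled_curve(cv$points[1:k, ], cv$label, cv$side),
         labeled_curve(cv$points[k:n, ], cv$label, cv$side))
  }), recursive = FALSE)
  r3 <- suppressWarnings(match_curves(endo, curve_set(frags)))
  expect_equal(r3$per_curve$mean_distance, r1$per_curve$mean_distance,
               tolerance = 1e-12)
})

test_that("summarize_reports reproduces the published count arithmetic", {
  tab <- human_count_table()
  reports <- lapply(seq_len(nrow(tab)), function(i)
    match_report(tab[i, "TC-E"], tab[i, "NS-E"], tab[i, "TC-B"],
                 tab[i, "NS-B"], tab[i, "NC-EB"], tab[i, "NS-EB"],
                 specimen = tab$specimen[i]))
  s <- summarize_reports(reports)
  mean_row <- s[s$specimen == "Mean", ]
  expect_identical(as.integer(mean_row[["NC-EB"]]), 143L)
  expect_identical(as.integer(mean_row[["TC-B"]]), 167L)
  expect_identical(as.integer(mean_row[["NS-EB"]]), 14L)
  expect_identical(as.integer(round(mean_row[["matched-pct"]])), 80L)
  # single report: mean row equals the report
  s1 <- summarize_reports(reports[1])
  expect_identical(as.integer(s1[2, "TC-E"]), 139L)
})

test_that("distance_field collapses onto curves and never overshoots", {
  sph <- icosphere(3, radius = 20)
  eq <- sph$vertices[abs(sph$vertices[, 3]) < 1, ]
  eq <- eq[order(atan2(eq[, 2], eq[, 1])), ]
  c1 <- labeled_curve(eq[1:10, ], "central")
  c2 <- labeled_curve(sweep(eq[1:10, ], 2, c(0, 0, 15), "+") * 0.8, "lunate")
  cs <- curve_set(list(c1, c2), "endocast")
  rep <- match_report(2, 2, 2, 2, 2, 0, per_curve = data.frame(
    curve = 1:2, label = c("central", "lunate"), mean_distance = c(4, 8),
    matched = c(TRUE, TRUE)))
  fld <- distance_field(sph, rep, cs, influence_radius = 10)
  on_curve <- which.min(dist_to_polyline(sph$vertices, c1))
  expect_equal(fld$values[on_curve], 4, tolerance = 0.05)
  vals <- fld$values[!fld$mask]
  expect_true(all(vals >= 4 - 1e-9 & vals <= 8 + 1e-9))
  # all curves matched at the same distance: constant field
  rep2 <- match_report(2, 2, 2, 2, 2, 0, per_curve = data.frame(
    curve = 1:2, label = c("central", "lunate"), mean_distance = c(5, 5),
    matched = c(TRUE, TRUE)))
  fld2 <- distance_field(sph, rep2, cs, influence_radius = 10)
  expect_true(all(abs(fld2$values[!fld2$mask] - 5) < 1e-9))
  # vertices nearest an unmatched curve are sentinel-masked
  rep3 <- match_report(2, 2, 2, 2, 1, 1, per_curve = data.frame(
    curve = 1:2, label = c("central", "lunate"),
    mean_distance = c(4, NA), matched = c(TRUE, FALSE)))
  fld3 <- distance_field(sph, rep3, cs, influence_radius = 10)
  near2 <- dist_to_polyline(sph$vertices, c2) <
    dist_to_polyline(sph$vertices, c1)
  expect_true(all(fld3$mask[near2]))
})

test_that("displacement_map measures surface offsets and clips for rendering", {
  s <- icosphere(3, radius = 20)
  expect_true(all(displacement_map(s, s)$values == 0))
  inflated <- triangle_mesh(s$vertices * 22 / 20, s$faces)
  dm <- displacement_map(s, inflated)
  expect_true(all(abs(dm$values - 2) < 0.05))
  far <- triangle_mesh(s$vertices * 35 / 20, s$faces)
  dm2 <- displacement_map(s, far, render_clip = 5)
  clipped <- attr(dm2, "clipped")
  expect_true(all(dm2$values >= clipped))
  expect_true(all(clipped <= 5))
})

test_that("match_report invariants are enforced", {
  expect_error(match_report(5, 2, 5, 2, 6, 0))       # NC_EB > TC_E
  expect_error(match_report(5, 2, 5, 2, 3, 3))       # NC+NS > TC_E
  expect_error(match_report(5, 6, 5, 2, 3, 1))       # NS_E > TC_E
  expect_silent(match_report(5, 2, 5, 2, 3, 2))
})
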