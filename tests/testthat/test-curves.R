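test_that("labeled_curve validates its invariants", {
  expect_error(labeled_curve(matrix(1:3, 1, 3)), "at least 2")
  expect_error(labeled_curve(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  cv <- labeled_curve(rbind(c(0, 0, 0), c(3, 4, 0)), "central", "left")
  expect_equal(curve_length(cv), 5)
})

test_that("curve sets round-trip through JSON losslessly", {
  set.seed(12)
  cs <- random_curve_set(5, c("central", "lunate", "sylvian"),
                         source = "endocast")
  cs$curves[[1]]$strength <- 0.123456789012345
  path <- withr::local_tempfile(fileext = ".json")
  write_curves(cs, path)
  cs2 <- read_curves(path)
  expect_identical(length(cs2), length(cs))
  expect_identical(cs2$source, cs$source)
  for (i in seq_along(cs$curves)) {
    expect_lt(max(abs(cs2$curves[[i]]$points - cs$curves[[i]]$points)), 1e-9)
    expect_identical(cs2$curves[[i]]$label, cs$curves[[i]]$label)
    expect_identical(cs2$curves[[i]]$side, cs$curves[[i]]$side)
  }
  # empty set round trip
  p2 <- withr::local_tempfile(fileext = ".json")
  write_curves(curve_set(list(), "brain-hull"), p2)
  e <- read_curves(p2)
  expect_length(e$curves, 0)
  expect_identical(e$source, "brain-hull")
})

test_that("unknown extra fields are ignored with a warning; bad files error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"format":"endocastr-curves","version":1,',
                    '"source":"endocast","operator":"someone",',
                    '"curves":[{"label":"central","side":"left",',
                    '"strength":0.2,"color":"red",',
                    '"points":[[0,0,0],[1,0,0],[2,0.5,0]]}]}'), path)
  expect_warning(
    expect_warning(cs <- read_curves(path), "unknown fields in curve file"),
    "record 1: ignoring unknown fields")
  expect_identical(cs$curves[[1]]$label, "central")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format":"something-else","curves":[]}', bad)
  expect_error(read_curves(bad), "format")
  mal <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"format":"endocastr-curves","version":1,"curves":',
                    '[{"side":"left","points":[[0,0,0],[1,0,0]]}]}'), mal)
  expect_error(read_curves(mal), "record 1")
})

test_that("label_by_reference keeps identity and applies the distance rule", {
  set.seed(13)
  ref <- random_curve_set(6, sulcus_vocabulary()[1:6])
  # detected = reference: every curve keeps its own label
  lab <- label_by_reference(ref, ref, max_assign_dist = 5)
  expect_identical(vapply(lab$curves, function(cv) cv$label, ""),
                   vapply(ref$curves, function(cv) cv$label, ""))
  # a curve 3 mm from "central" with a 5 mm threshold gets "central"
  base <- labeled_curve(rbind(c(0, 0, 0), c(20, 0, 0)), "central", "left")
  det <- curve_set(list(labeled_curve(rbind(c(2, 3, 0), c(18, 3, 0)))))
  out <- label_by_reference(det, curve_set(list(base)), 5)
  expect_identical(out$curves[[1]]$label, "central")
  expect_identical(out$curves[[1]]$side, "left")
  # beyond the threshold: unlabeled
  far <- curve_set(list(labeled_curve(rbind(c(0, 30, 0), c(20, 30, 0)))))
  out2 <- label_by_reference(far, curve_set(list(base)), 5)
  expect_identical(out2$curves[[1]]$label, "unlabeled")
})

test_that("labeling equals brute-force nearest-reference assignment", {
  set.seed(14)
  ref <- random_curve_set(8, sulcus_vocabulary()[1:8])
  det <- random_curve_set(15, "x")
  out <- label_by_reference(det, ref, max_assign_dist = 12)
  for (i in seq_along(det$curves)) {
    d <- vapply(ref$curves, function(rf)
      mean(dist_to_polyline(det$curves[[i]]$points, rf)), 0)
    expected <- if (min(d) <= 12) ref$curves[[which.min(d)]]$label
                else "unlabeled"
    expect_identical(out$curves[[i]]$label, expected)
    # geometry never modified
    expect_identical(out$curves[[i]]$points, det$curves[[i]]$points)
  }
})

test_that("labeling is invariant to input curve order", {
  set.seed(15)
  ref <- random_curve_set(5, sulcus_vocabulary()[1:5])
  det <- random_curve_set(9, "x")
  out1 <- label_by_reference(det, ref, 10)
  perm <- sample(length(det$curves))
  det2 <- curve_set(det$curves[perm], det$source)
  out2 <- label_by_reference(det2, ref, 10)
  l1 <- vapply(out1$curves, function(cv) cv$label, "")
  l2 <- vapply(out2$curves, function(cv) cv$label, "")
  expect_identical(l2, l1[perm])
})
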