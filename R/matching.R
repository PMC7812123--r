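#' Mean closest-point distance from an endocast curve to same-label brain curves
#'
#' For each point of the endocast curve, the minimum distance to any segment
#' of the brain curves carrying the same label is computed (point-to-segment
#' projection, so the measure is resolution independent); the curve distance
#' is the mean of these minima. The measure is directional
#' (endocast to brain). Returns `NA` when no same-label brain curve exists.
#'
#' @param endo_curve a [labeled_curve()] from the endocast.
#' @param brain_curves a [curve_set()] (or list of curves) restricted to, or
#'   filtered by, `endo_curve`'s label; curves with other labels are ignored.
#' @return mean distance in mm, or `NA_real_`.
#' @export
curve_distance <- function(endo_curve, brain_curves) {
  curves <- if (inherits(brain_curves, "curve_set")) brain_curves$curves
            else brain_curves
  same <- Filter(function(cv) cv$label == endo_curve$label, curves)
  if (length(same) == 0) return(NA_real_)
  A <- do.call(rbind, lapply(same, function(cv)
    cv$points[-nrow(cv$points), , drop = FALSE]))
  B <- do.call(rbind, lapply(same, function(cv)
    cv$points[-1, , drop = FALSE]))
  mean(cpp_min_dist_segments(endo_curve$points, A, B))
}

#' Curve-matching report
#'
#' Container for the count statistics of one individual's brain/endocast
#' comparison: total curves on the endocast (`TC_E`) and brain hull (`TC_B`),
#' distinct sulci per surface (`NS_E`, `NS_B`), curves identified in both at
#' a mean distance below the threshold (`NC_EB`), and endocast curves without
#' a corresponding brain curve under the criterion (`NS_EB`).
#'
#' @param tc_e,ns_e,tc_b,ns_b,nc_eb,ns_eb integer counts.
#' @param tau matching threshold in mm.
#' @param per_curve optional data frame of per-curve results.
#' @param specimen optional identifier.
#' @return object of class `match_report`.
#' @export
match_report <- function(tc_e, ns_e, tc_b, ns_b, nc_eb, ns_eb, tau = 10,
                         per_curve = NULL, specimen = NA_character_) {
  stopifnot(tau > 0, nc_eb <= tc_e, nc_eb + ns_eb <= tc_e, ns_e <= tc_e,
            ns_b <= tc_b)
  structure(list(TC_E = as.integer(tc_e), NS_E = as.integer(ns_e),
                 TC_B = as.integer(tc_b), NS_B = as.integer(ns_b),
                 NC_EB = as.integer(nc_eb), NS_EB = as.integer(ns_eb),
                 tau = tau, per_curve = per_curve,
                 specimen = as.character(specimen)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(paste0("match_report%s: TC-E %d, NS-E %d, TC-B %d, NS-B %d, ",
                     "NC-EB %d, NS-EB %d (tau = %g mm)\n"),
              if (is.na(x$specimen)) "" else paste0(" [", x$specimen, "]"),
              x$TC_E, x$NS_E, x$TC_B, x$NS_B, x$NC_EB, x$NS_EB, x$tau))
  invisible(x)
}

#' Match endocast curves against transported brain curves
#'
#' An endocast curve is matched when its mean closest-point distance to the
#' same-label brain curves ([curve_distance()]) exists and is strictly less
#' than `tau` (a distance of exactly `tau` does not match). The default
#' threshold of 10 mm corresponds to the typical maximum distance between two
#' neighbouring sulci. All same-label brain fragments are used jointly, so
#' matching is invariant to splitting a brain curve into fragments.
#'
#' @param endo a [curve_set()] of endocast curves.
#' @param brain_deformed a [curve_set()] of brain-hull curves already
#'   transported into the endocast frame.
#' @param tau matching threshold in mm (default 10).
#' @param specimen optional identifier carried into the report.
#' @return a [match_report()]; `per_curve` holds one row per endocast curve
#'   with its label, mean distance and matched flag.
#' @export
match_curves <- function(endo, brain_deformed, tau = 10,
                         specimen = NA_character_) {
  stopifnot(tau > 0)
  endo_labs <- vapply(endo$curves, function(cv) cv$label, "")
  brain_labs <- vapply(brain_deformed$curves, function(cv) cv$label, "")
  only_endo <- setdiff(setdiff(endo_labs, "unlabeled"), brain_labs)
  if (length(only_endo))
    warning("endocast labels absent from the brain set: ",
            paste(unique(only_endo), collapse = ", "))
  d <- vapply(endo$curves, curve_distance, 0, brain_curves = brain_deformed)
  matched <- !is.na(d) & d < tau
  per_curve <- data.frame(
    curve = seq_along(endo$curves),
    label = endo_labs,
    mean_distance = d,
    matched = matched,
    stringsAsFactors = FALSE)
  match_report(
    tc_e = length(endo$curves),
    ns_e = length(curve_labels(endo)),
    tc_b = length(brain_deformed$curves),
    ns_b = length(curve_labels(brain_deformed)),
    nc_eb = sum(matched),
    ns_eb = sum(!matched),
    tau = tau, per_curve = per_curve, specimen = specimen)
}

#' Summary table over several match reports
#'
#' One row per report with the six count columns (headers `TC-E`, `NS-E`,
#' `TC-B`, `NS-B`, `NC-EB`, `NS-EB`) plus the per-report matched fraction
#' `NC-EB / TC-E` in percent, and a final `Mean` row: arithmetic column means
#' rounded half-up to integers for the counts, plain mean for the percentage.
#'
#' @param reports list of [match_report()] objects.
#' @return a `data.frame` (CSV-writable).
#' @export
summarize_reports <- function(reports) {
  if (inherits(reports, "match_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "match_report")))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(
      specimen = if (is.na(r$specimen)) paste0("I", i) else r$specimen,
      `TC-E` = r$TC_E, `NS-E` = r$NS_E, `TC-B` = r$TC_B, `NS-B` = r$NS_B,
      `NC-EB` = r$NC_EB, `NS-EB` = r$NS_EB,
      `matched-pct` = 100 * r$NC_EB / r$TC_E,
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  round_half_up <- function(x) floor(x + 0.5)
  counts <- c("TC-E", "NS-E", "TC-B", "NS-B", "NC-EB", "NS-EB")
  mean_row <- data.frame(
    specimen = "Mean",
    as.list(setNames(round_half_up(colMeans(tab[counts])), counts)),
    `matched-pct` = mean(tab[["matched-pct"]]),
    check.names = FALSE, stringsAsFactors = FALSE)
  rbind(tab, mean_row)
}

#' Published five-individual curve count table
#'
#' Curve and sulcus counts from a published MRI/CT comparison of the brain
#' hull and endocast in five adult humans, shipped as worked-example input for
#' [summarize_reports()] arithmetic.
#' @return data frame with columns `specimen`, `TC-E`, `NS-E`, `TC-B`,
#'   `NS-B`, `NC-EB`, `NS-EB`.
#' @export
human_count_table <- function() {
  read.csv(system.file("extdata", "human_counts.csv", package = "endocastr"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' Per-vertex scalar field on a mesh with a sentinel mask
#'
#' @param values numeric per-vertex values (mm); finite where unmasked.
#' @param mask logical per-vertex; `TRUE` marks "not found" vertices.
#' @return object of class `scalar_field`.
#' @export
scalar_field <- function(values, mask = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(mask),
            all(is.finite(values[!mask])), all(values[!mask] >= 0))
  structure(list(values = as.numeric(values), mask = as.logical(mask)),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar_field:", length(x$values), "vertices,", sum(x$mask),
      "masked\n")
  if (any(!x$mask))
    cat("  range (unmasked):", format(range(x$values[!x$mask]),
                                      digits = 4), "mm\n")
  invisible(x)
}

#' Extrapolate per-curve matching distances onto the endocast surface
#'
#' Every vertex within `influence_radius` of a matched curve receives an
#' inverse-distance-weighted blend of the nearby matched curves' mean
#' distances (so values never overshoot the input min/max). Vertices whose
#' nearest curve is unmatched -- endocast sulci not found on the brain -- are
#' sentinel-masked, as are vertices with no curve within reach.
#'
#' @param endocast_mesh the endocast [triangle_mesh()].
#' @param report the [match_report()] from [match_curves()].
#' @param endo_curves the endocast [curve_set()] the report refers to.
#' @param influence_radius blending radius in mm; defaults to the report's
#'   matching threshold.
#' @return a [scalar_field()] over the mesh vertices.
#' @export
distance_field <- function(endocast_mesh, report, endo_curves,
                           influence_radius = report$tau) {
  stopifnot(length(endo_curves$curves) == nrow(report$per_curve))
  V <- endocast_mesh$vertices
  nc <- length(endo_curves$curves)
  D <- matrix(Inf, nrow(V), max(nc, 1))
  for (i in seq_len(nc))
    D[, i] <- dist_to_polyline(V, endo_curves$curves[[i]])
  matched <- report$per_curve$matched
  vals <- numeric(nrow(V))
  mask <- rep(TRUE, nrow(V))
  if (nc > 0) {
    nearest <- max.col(-D, ties.method = "first")
    in_reach <- D <= influence_radius
    Wm <- 1 / (D + 1e-9)
    Wm[, !matched] <- 0
    Wm[!in_reach] <- 0
    wsum <- rowSums(Wm)
    ok <- matched[nearest] & wsum > 0
    md <- report$per_curve$mean_distance
    md[!matched] <- 0  # zero weight anyway
    vals[ok] <- (Wm %*% md)[ok] / wsum[ok]
    mask <- !ok
  }
  scalar_field(vals, mask)
}

#' Surface displacement map between deformed brain hull and endocast
#'
#' Per-vertex closest-point distance (point-to-triangle) from the endocast
#' vertices to the deformed brain-hull surface. Raw values are stored; a copy
#' clipped at `render_clip` (the 0-5 mm rendering scale) is attached as
#' attribute `clipped`.
#'
#' @param deformed_brain_hull,endocast [triangle_mesh()] objects in a common
#'   frame.
#' @param render_clip clip value in mm for the visualization copy.
#' @return a [scalar_field()] over the endocast vertices with attribute
#'   `clipped`.
#' @export
displacement_map <- function(deformed_brain_hull, endocast, render_clip = 5) {
  d <- closest_point_mesh(deformed_brain_hull, endocast$vertices)$distance
  out <- scalar_field(d)
  attr(out, "clipped") <- pmin(d, render_clip)
  out
}
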