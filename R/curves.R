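#' Labelled 3D polyline curve
#'
#' An ordered polyline in mm with a sulcus label, a hemisphere side and a
#' detection strength (mean absolute principal curvature along the curve).
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2, consecutive
#'   points distinct.
#' @param label sulcus name (free vocabulary, e.g. `"central"`) or
#'   `"unlabeled"`.
#' @param side one of `"left"`, `"right"`, `"midline"`, `"unassigned"`.
#' @param strength mean absolute curvature along the curve (1/mm).
#' @return An object of class `labeled_curve`.
#' @export
labeled_curve <- function(points, label = "unlabeled", side = "unassigned",
                          strength = NA_real_) {
  points <- as_points(points)
  if (nrow(points) < 2) stop("a curve needs at least 2 points")
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive curve points must be distinct")
  side <- match.arg(side, c("left", "right", "midline", "unassigned"))
  structure(list(points = points, label = as.character(label), side = side,
                 strength = as.numeric(strength)),
            class = "labeled_curve")
}

#' Arc length of a polyline curve
#' @param curve a [labeled_curve()].
#' @return length in mm.
#' @export
curve_length <- function(curve) {
  p <- curve$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Set of labelled curves from one surface
#' @param curves list of [labeled_curve()] objects.
#' @param source which surface the curves come from: `"brain-hull"`,
#'   `"endocast"` or `"unknown"`.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves = list(), source = "unknown") {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, TRUE, "labeled_curve")))
  source <- match.arg(source, c("brain-hull", "endocast", "unknown"))
  structure(list(curves = curves, source = source), class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("curve_set (", x$source, "): ", length(x$curves), " curves, ",
      length(curve_labels(x)), " distinct labels\n", sep = "")
  invisible(x)
}

#' @export
length.curve_set <- function(x) length(x$curves)

#' Distinct labels in a curve set (excluding "unlabeled")
#' @param curves a [curve_set()].
#' @return character vector of labels.
#' @export
curve_labels <- function(curves) {
  l <- unique(vapply(curves$curves, function(cv) cv$label, ""))
  setdiff(l, "unlabeled")
}

#' Reference vocabulary of human sulcus names
#'
#' The sulcus names used in endocast atlases for labelling detected curves.
#' Plain word list only; no atlas geometry is shipped.
#' @return character vector of sulcus names.
#' @export
sulcus_vocabulary <- function() {
  readLines(system.file("extdata", "sulcus_labels.txt", package = "endocastr"),
            warn = FALSE)
}

#' Minimum distances from points to a polyline
#'
#' Point-to-segment distances (not point-to-vertex), so results are
#' resolution independent.
#' @param points n x 3 matrix (mm).
#' @param curve a [labeled_curve()] or an n x 3 matrix of polyline points.
#' @return numeric vector: for each point, distance to the nearest segment.
#' @export
dist_to_polyline <- function(points, curve) {
  p <- if (inherits(curve, "labeled_curve")) curve$points else as_points(curve)
  n <- nrow(p)
  cpp_min_dist_segments(as_points(points), p[-n, , drop = FALSE],
                        p[-1, , drop = FALSE])
}

#' Write a curve set to a versioned JSON file
#'
#' Lossless round trip: points keep full double precision and labels are
#' stored exactly.
#' @param curves a [curve_set()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  doc <- list(
    format = "endocastr-curves",
    version = 1L,
    source = curves$source,
    curves = lapply(curves$curves, function(cv) list(
      label = cv$label, side = cv$side, strength = cv$strength,
      points = unname(cv$points))))
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                           na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a curve set from a JSON file
#'
#' Unknown extra fields are ignored with a warning.
#' @param path file path written by [write_curves()].
#' @return a [curve_set()].
#' @export
read_curves <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed curve file: ",
                                           conditionMessage(e)))
  if (!identical(doc$format, "endocastr-curves"))
    stop("not an endocastr curve file (missing format header)")
  if (is.null(doc$version) || doc$version > 1)
    stop("unsupported curve file version: ", doc$version)
  known <- c("format", "version", "source", "curves")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("ignoring unknown fields in curve file: ",
            paste(extra, collapse = ", "))
  curves <- lapply(seq_along(doc$curves), function(i) {
    rec <- doc$curves[[i]]
    for (fld in c("label", "points"))
      if (is.null(rec[[fld]]))
        stop(sprintf("malformed curve record %d: missing '%s'", i, fld))
    kn <- c("label", "side", "strength", "points")
    ex <- setdiff(names(rec), kn)
    if (length(ex))
      warning(sprintf("curve record %d: ignoring unknown fields %s", i,
                      paste(ex, collapse = ", ")))
    pts <- do.call(rbind, lapply(rec$points, as.numeric))
    labeled_curve(pts, label = rec$label,
                  side = if (is.null(rec$side)) "unassigned" else rec$side,
                  strength = if (is.null(rec$strength) ||
                                 !is.numeric(rec$strength)) NA_real_
                             else rec$strength)
  })
  curve_set(curves, source = if (is.null(doc$source)) "unknown" else
    doc$source)
}

#' Label detected curves against a labelled reference set
#'
#' Each detected curve receives the label (and side) of the reference curve
#' minimizing the mean closest-point distance from the detected curve's points
#' to the reference polyline, provided that distance is at most
#' `max_assign_dist`; otherwise it stays `"unlabeled"`. Several detected
#' fragments may share one label, mirroring sulci that are incomplete or split
#' into fragments. Ties are broken by greater reference overlap length, then
#' lexicographically by label. Curve geometry is never modified.
#'
#' @param detected a [curve_set()] of detected curves.
#' @param reference a labelled [curve_set()].
#' @param max_assign_dist assignment threshold in mm.
#' @return a [curve_set()] with labels assigned.
#' @export
label_by_reference <- function(detected, reference, max_assign_dist = 5) {
  if (length(reference$curves) == 0) stop("empty reference curve set")
  ref_lens <- vapply(reference$curves, curve_length, 0)
  ref_labs <- vapply(reference$curves, function(cv) cv$label, "")
  out <- lapply(detected$curves, function(cv) {
    d <- vapply(reference$curves,
                function(rf) mean(dist_to_polyline(cv$points, rf)), 0)
    ok <- which(d <= max_assign_dist)
    if (length(ok) == 0) {
      cv$label <- "unlabeled"
      cv$side <- "unassigned"
      return(cv)
    }
    best <- min(d[ok])
    cand <- ok[d[ok] <= best + 1e-12]
    if (length(cand) > 1) {  # tie-break: longer overlap, then label order
      cand <- cand[order(-ref_lens[cand], ref_labs[cand])]
    }
    pick <- cand[1]
    cv$label <- reference$curves[[pick]]$label
    cv$side <- reference$curves[[pick]]$side
    cv
  })
  curve_set(out, source = detected$source)
}
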