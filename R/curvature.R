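#' Per-vertex principal curvatures and extremality coefficients
#'
#' Fits a local cubic height field over a geodesic-like neighbourhood of each
#' vertex (edge-path distances within `neighborhood_radius`) in the frame of
#' the outward vertex normal. Principal curvatures and directions come from
#' the quadratic part via the shape operator; the extremality coefficient of
#' each principal curvature (its directional derivative along its own
#' principal direction, in 1/mm^2) comes from the cubic correction terms.
#'
#' Sign convention: surfaces convex with respect to the outward normal have
#' positive curvature, so a sphere gives `kmax = kmin = +1/r` and the floor of
#' a sulcal groove has `kmin < 0` across the groove.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param neighborhood_radius fitting radius in mm; default 2.5 times the mean
#'   edge length (must be at least 2 edge lengths for a stable fit).
#' @return An object of class `curvature_field`: list with per-vertex `kmax`,
#'   `kmin` (1/mm), unit tangent `dmax`, `dmin` (n x 3), and extremality
#'   `emax`, `emin` (1/mm^2).
#' @export
estimate_curvature <- function(mesh, neighborhood_radius = NULL) {
  if (!is_watertight(mesh)) stop("estimate_curvature requires a watertight mesh")
  mel <- mean_edge_length(mesh)
  if (is.null(neighborhood_radius)) neighborhood_radius <- 2.5 * mel
  if (neighborhood_radius < 2 * mel)
    stop("neighborhood_radius must be at least 2x the mean edge length")
  n <- vertex_normals(mesh)
  out <- cpp_curvature(mesh$vertices, mesh$faces, n, neighborhood_radius, 12L)
  structure(out, class = "curvature_field",
            radius = neighborhood_radius)
}

#' @export
print.curvature_field <- function(x, ...) {
  cat("curvature_field:", length(x$kmax), "vertices\n")
  cat(sprintf("  kmax [%g, %g] 1/mm, kmin [%g, %g] 1/mm\n",
              min(x$kmax), max(x$kmax), min(x$kmin), max(x$kmin)))
  invisible(x)
}

#' Trace ravine (or ridge) lines on a mesh
#'
#' Detects sulcal imprints as curvature-extremal lines: zero crossings of the
#' extremality coefficient `emin` on mesh edges where `kmin` is below
#' `-k_threshold` (ravines, concave furrows). Crossings in each triangle are
#' linked into ordered polylines; at triangles with three crossing edges the
#' two with the strongest interpolated `|kmin|` are joined and the third
#' starts its own polyline. Principal-direction sign ambiguity is resolved
#' per edge by aligning the two vertex directions before the zero-crossing
#' test. Set `mode = "ridge"` for the symmetric convex case (zero crossings
#' of `emax` where `kmax > k_threshold`).
#'
#' @param mesh a [triangle_mesh()].
#' @param field a [estimate_curvature()] result for `mesh`.
#' @param k_threshold curvature threshold in 1/mm; default the 75th
#'   percentile of `|kmin|` (or `|kmax|` in ridge mode) over the mesh.
#' @param min_length polylines shorter than this (mm) are discarded.
#' @param mode `"ravine"` (default) or `"ridge"`.
#' @param join_gap chains whose endpoints are closer than this (mm) are
#'   bridged into one polyline before length filtering, countering the
#'   fragmentation inherent to crest-line tracing; defaults to twice the mean
#'   edge length. Keep it well below the sulcal spacing. 0 disables joining.
#' @return a [curve_set()] of unlabelled curves; empty when nothing passes
#'   the thresholds.
#' @export
trace_ravines <- function(mesh, field, k_threshold = NULL, min_length = 10,
                          mode = c("ravine", "ridge"), join_gap = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "curvature_field"),
            length(field$kmin) == nrow(mesh$vertices))
  if (mode == "ravine") {
    k <- field$kmin
    ex <- field$emin
    dirs <- field$dmin
    pass <- function(kv) kv < -k_threshold
  } else {
    k <- field$kmax
    ex <- field$emax
    dirs <- field$dmax
    pass <- function(kv) kv > k_threshold
  }
  if (is.null(k_threshold)) k_threshold <- as.numeric(quantile(abs(k), 0.75))

  # per-edge zero crossings with direction alignment
  edges <- mesh_edges(mesh)
  a <- edges[, 1]
  b <- edges[, 2]
  s <- sign(rowSums(dirs[a, , drop = FALSE] * dirs[b, , drop = FALSE]))
  s[s == 0] <- 1
  eb <- ex[b] * s
  cross <- (ex[a] * eb < 0) & pass(k[a]) & pass(k[b])
  cidx <- which(cross)
  if (length(cidx) == 0) return(curve_set(list(), source = "unknown"))
  t <- ex[a[cidx]] / (ex[a[cidx]] - eb[cidx])
  cpts <- (1 - t) * mesh$vertices[a[cidx], , drop = FALSE] +
    t * mesh$vertices[b[cidx], , drop = FALSE]
  ck <- (1 - t) * k[a[cidx]] + t * k[b[cidx]]
  # map mesh edge -> crossing id
  ekey <- paste(a, b)
  crossing_of <- setNames(seq_along(cidx), ekey[cidx])

  # face segments joining crossings
  f <- mesh$faces
  fe <- cbind(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
              paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
              paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])))
  seg_a <- integer(0)
  seg_b <- integer(0)
  fc <- matrix(crossing_of[fe], ncol = 3)
  ncross <- rowSums(!is.na(fc))
  two <- which(ncross == 2)
  if (length(two)) {
    pairs <- t(apply(fc[two, , drop = FALSE], 1, function(r) r[!is.na(r)]))
    seg_a <- c(seg_a, pairs[, 1])
    seg_b <- c(seg_b, pairs[, 2])
  }
  three <- which(ncross == 3)
  for (fi in three) {
    ids <- fc[fi, ]
    str <- abs(ck[ids])
    keep <- ids[order(-str)[1:2]]  # join the two strongest crossings
    seg_a <- c(seg_a, keep[1])
    seg_b <- c(seg_b, keep[2])
  }
  if (length(seg_a) == 0) return(curve_set(list(), source = "unknown"))

  # walk chains: each crossing has degree <= 2
  nb <- vector("list", length(cidx))
  for (i in seq_along(seg_a)) {
    nb[[seg_a[i]]] <- c(nb[[seg_a[i]]], seg_b[i])
    nb[[seg_b[i]]] <- c(nb[[seg_b[i]]], seg_a[i])
  }
  deg <- lengths(nb)
  visited <- logical(length(cidx))
  chains <- list()
  walk <- function(start) {
    chain <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      nxt <- nb[[cur]][!visited[nb[[cur]]]]
      if (length(nxt) == 0) break
      cur <- nxt[1]
      visited[cur] <<- TRUE
      chain <- c(chain, cur)
    }
    chain
  }
  ends <- which(deg == 1 & !visited)
  for (start in ends) if (!visited[start]) chains <- c(chains, list(walk(start)))
  # remaining are cycles (or isolated crossings)
  for (start in which(!visited & deg > 0))
    if (!visited[start]) chains <- c(chains, list(walk(start)))

  if (is.null(join_gap)) join_gap <- 2 * mean_edge_length(mesh)
  polys <- list()
  for (ch in chains) {
    if (length(ch) < 2) next
    pts <- cpts[ch, , drop = FALSE]
    dd <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
    keep <- c(TRUE, dd > 1e-12)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2) next
    polys <- c(polys, list(list(points = pts, k = abs(ck[ch])[keep])))
  }
  if (join_gap > 0) polys <- join_polylines(polys, join_gap)
  curves <- list()
  for (pl in polys) {
    cv <- labeled_curve(pl$points, strength = mean(pl$k))
    if (curve_length(cv) >= min_length) curves <- c(curves, list(cv))
  }
  curve_set(curves, source = "unknown")
}

# internal: greedily bridge polylines whose endpoints are within `gap` mm
join_polylines <- function(polys, gap) {
  repeat {
    n <- length(polys)
    if (n < 2) return(polys)
    ends <- do.call(rbind, lapply(seq_len(n), function(i) {
      p <- polys[[i]]$points
      rbind(c(i, 1, p[1, ]), c(i, 2, p[nrow(p), ]))
    }))
    best <- c(Inf, 0, 0)
    for (a in seq_len(nrow(ends) - 1)) {
      d <- sqrt(rowSums(sweep(ends[(a + 1):nrow(ends), 3:5, drop = FALSE],
                              2, ends[a, 3:5])^2))
      d[ends[(a + 1):nrow(ends), 1] == ends[a, 1]] <- Inf
      j <- which.min(d)
      if (d[j] < best[1]) best <- c(d[j], a, a + j)
    }
    if (best[1] > gap) return(polys)
    e1 <- ends[best[2], ]
    e2 <- ends[best[3], ]
    p1 <- polys[[e1[1]]]
    p2 <- polys[[e2[1]]]
    pts1 <- p1$points
    pts2 <- p2$points
    if (e1[2] == 1) { pts1 <- pts1[nrow(pts1):1, , drop = FALSE]
                      p1$k <- rev(p1$k) }
    if (e2[2] == 2) { pts2 <- pts2[nrow(pts2):1, , drop = FALSE]
                      p2$k <- rev(p2$k) }
    if (sqrt(sum((pts1[nrow(pts1), ] - pts2[1, ])^2)) < 1e-9)
      pts2 <- pts2[-1, , drop = FALSE]
    merged <- list(points = rbind(pts1, pts2), k = c(p1$k, p2$k))
    polys <- c(polys[-c(e1[1], e2[1])], list(merged))
  }
}

#' Filter curves by length and strength
#'
#' Returns the subset of curves passing both thresholds; order is preserved
#' and no curve is modified.
#' @param curves a [curve_set()].
#' @param min_length minimum arc length (mm).
#' @param min_strength minimum mean absolute curvature (1/mm); curves with
#'   `NA` strength pass only when `min_strength` is 0.
#' @return filtered [curve_set()].
#' @export
filter_curves <- function(curves, min_length = 0, min_strength = 0) {
  keep <- vapply(curves$curves, function(cv) {
    len_ok <- curve_length(cv) >= min_length
    str_ok <- if (min_strength <= 0) TRUE
              else !is.na(cv$strength) && cv$strength >= min_strength
    len_ok && str_ok
  }, TRUE)
  curve_set(curves$curves[keep], source = curves$source)
}
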