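#' Triangle mesh in world coordinates (mm)
#'
#' A minimal triangle-mesh container: an `n x 3` matrix of vertex positions in
#' mm and an `m x 3` integer matrix of 1-based vertex indices per face.
#' Surfaces produced by [shrink_wrap()] and [resample_mesh()] are closed
#' (watertight) and consistently oriented with outward normals.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) stop("faces must be m x 3")
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.1f, %.1f] y [%.1f, %.1f] z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Face normals, areas and centers
#'
#' `face_normals` returns unit outward normals (m x 3) given consistent
#' counter-clockwise winding; `face_areas` the triangle areas (mm^2);
#' `face_centers` the centroids (m x 3, mm).
#' @param mesh a [triangle_mesh()].
#' @name face_geometry
#' @export
face_normals <- function(mesh) {
  n <- face_cross(mesh)
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' @rdname face_geometry
#' @export
face_areas <- function(mesh) {
  sqrt(rowSums(face_cross(mesh)^2)) / 2
}

#' @rdname face_geometry
#' @export
face_centers <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# internal: unnormalized face normals (cross products)
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Area-weighted outward vertex normals
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_cross(mesh)  # area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (k in 1:3) {
      s <- rowsum(fn[, k], mesh$faces[, c], reorder = FALSE)
      idx <- as.integer(rownames(s))
      n[idx, k] <- n[idx, k] + s
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' Undirected edge list of a mesh
#' @param mesh a [triangle_mesh()].
#' @return 2-column integer matrix, one row per undirected edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Watertightness and orientation check
#'
#' A closed, consistently oriented triangle mesh has every undirected edge in
#' exactly two faces, traversed once in each direction.
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  dirkey <- paste(he[, 1], he[, 2])
  !any(duplicated(dirkey))
}

#' Euler characteristic V - E + F
#' @param mesh a [triangle_mesh()].
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh a closed [triangle_mesh()] with outward orientation.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Mean edge length of a mesh
#' @param mesh a [triangle_mesh()].
#' @return mean undirected edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Closest point on a mesh surface
#'
#' Exact point-to-triangle closest-point query, accelerated by a uniform grid.
#' @param mesh a [triangle_mesh()].
#' @param points n x 3 matrix of query points (mm).
#' @return list with `distance` (n), `point` (n x 3 closest surface points)
#'   and `face` (n, 1-based face index).
#' @export
closest_point_mesh <- function(mesh, points) {
  points <- as_points(points)
  cpp_closest_point_mesh(mesh$vertices, mesh$faces, points)
}

#' Signed inside test for points against a closed mesh
#'
#' Uses the normal of the closest face; robust for the smooth closed surfaces
#' this package produces.
#' @param mesh a closed [triangle_mesh()] with outward normals.
#' @param points n x 3 matrix (mm).
#' @return logical vector, `TRUE` for points inside.
#' @export
point_in_mesh <- function(mesh, points) {
  points <- as_points(points)
  cp <- closest_point_mesh(mesh, points)
  fn <- face_normals(mesh)[cp$face, , drop = FALSE]
  rowSums((points - cp$point) * fn) < 0
}

#' Subdivided icosahedron sphere mesh
#'
#' @param subdivisions number of 1-to-4 midpoint subdivisions of the
#'   icosahedron (level L gives `20 * 4^L` faces).
#' @param center sphere center (mm).
#' @param radius sphere radius (mm).
#' @return a watertight [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 3, center = c(0, 0, 0), radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- triangle_mesh(v, f)
  for (i in seq_len(subdivisions)) {
    mesh <- subdivide_mesh(mesh)
    r <- sqrt(rowSums(mesh$vertices^2))
    mesh$vertices <- mesh$vertices / r
  }
  mesh$vertices <- sweep(mesh$vertices * radius, 2, center, "+")
  mesh
}

#' Midpoint 1-to-4 subdivision
#'
#' Splits every face into four by inserting edge midpoints (geometry is not
#' smoothed); used by [resample_mesh()] to upsample before exact decimation.
#' @param mesh a [triangle_mesh()].
#' @return subdivided [triangle_mesh()].
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uid <- paste(ekey[, 1], ekey[, 2])
  uniq <- !duplicated(uid)
  eu <- ekey[uniq, , drop = FALSE]
  mid <- (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2
  midx <- nrow(v) + match(uid, uid[uniq])
  nf <- nrow(f)
  m12 <- midx[1:nf]
  m23 <- midx[nf + 1:nf]
  m31 <- midx[2 * nf + 1:nf]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23),
                cbind(m12, m23, m31))
  triangle_mesh(rbind(v, mid), newf)
}

#' Resample a mesh to an exact face budget
#'
#' Upsamples by midpoint subdivision when needed, then decimates by
#' shortest-edge collapse to exactly `target_faces` faces. The default target
#' of 100,000 faces is the budget used to standardize brain-hull and endocast
#' meshes before comparison.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param target_faces exact face count of the output (even difference from
#'   the input count is required by edge-collapse parity on a closed mesh).
#' @return a [triangle_mesh()] with exactly `target_faces` faces.
#' @export
resample_mesh <- function(mesh, target_faces = 100000) {
  stopifnot(target_faces >= 4)
  if (!is_watertight(mesh)) stop("resample_mesh requires a watertight mesh")
  if (nrow(mesh$faces) == target_faces) return(mesh)
  while (nrow(mesh$faces) < target_faces) mesh <- subdivide_mesh(mesh)
  if (nrow(mesh$faces) == target_faces) return(mesh)
  out <- cpp_decimate(mesh$vertices, mesh$faces, as.integer(target_faces))
  triangle_mesh(out$vertices, out$faces)
}
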