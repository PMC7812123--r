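#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at continuous 0-based voxel
// coordinates. Points outside the grid get `background` (may be NA);
// with clamp_edge = true coordinates are clamped to the grid instead.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, double background,
                            bool clamp_edge) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (clamp_edge) {
      x = std::min(std::max(x, 0.0), nx - 1.0);
      y = std::min(std::max(y, 0.0), ny - 1.0);
      z = std::min(std::max(z, 0.0), nz - 1.0);
    } else if (x < 0 || y < 0 || z < 0 ||
               x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 >= nx - 1) i0 = nx - 2;
    if (j0 >= ny - 1) j0 = ny - 2;
    if (k0 >= nz - 1) k0 = nz - 2;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
#define V(i, j, k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

static inline double seg_dist2(double px, double py, double pz,
                               double ax, double ay, double az,
                               double bx, double by, double bz) {
  double ux = bx - ax, uy = by - ay, uz = bz - az;
  double wx = px - ax, wy = py - ay, wz = pz - az;
  double uu = ux * ux + uy * uy + uz * uz;
  double t = 0.0;
  if (uu > 0) {
    t = (wx * ux + wy * uy + wz * uz) / uu;
    if (t < 0) t = 0; else if (t > 1) t = 1;
  }
  double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance from each query point to a set of segments (A[i] -> B[i]).
// Degenerate segments (A == B) behave as points.
// [[Rcpp::export]]
NumericVector cpp_min_dist_segments(NumericMatrix P, NumericMatrix A,
                                    NumericMatrix B) {
  const int n = P.nrow(), m = A.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    for (int j = 0; j < m; ++j) {
      double d2 = seg_dist2(px, py, pz, A(j, 0), A(j, 1), A(j, 2),
                            B(j, 0), B(j, 1), B(j, 2));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
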