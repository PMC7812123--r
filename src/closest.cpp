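#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { out[0] = a[0]; out[1] = a[1]; out[2] = a[2]; return; }
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { out[0] = b[0]; out[1] = b[1]; out[2] = b[2]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = (d1 - d3 != 0) ? d1 / (d1 - d3) : 0.0;
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ab[k];
    return;
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { out[0] = c[0]; out[1] = c[1]; out[2] = c[2]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = (d2 - d6 != 0) ? d2 / (d2 - d6) : 0.0;
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double denom = (d4 - d3) + (d5 - d6);
    double t = denom != 0 ? (d4 - d3) / denom : 0.0;
    for (int k = 0; k < 3; ++k) out[k] = b[k] + t * (c[k] - b[k]);
    return;
  }
  double denom = va + vb + vc;
  double v = denom != 0 ? vb / denom : 0.0;
  double w = denom != 0 ? vc / denom : 0.0;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

struct TriGrid {
  double origin[3];
  double cell;
  int n[3];
  std::vector<std::vector<int> > bins;
  int idx(int i, int j, int k) const {
    return i + n[0] * (j + n[1] * k);
  }
};

// Closest point on a triangle mesh for each query point, accelerated by a
// uniform grid over triangle bounding boxes. F is 1-based.
// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int nf = F.nrow(), nq = Q.nrow();
  if (nf == 0) stop("mesh has no faces");
  TriGrid g;
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      if (V(i, k) < lo[k]) lo[k] = V(i, k);
      if (V(i, k) > hi[k]) hi[k] = V(i, k);
    }
  double ext = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  if (ext <= 0) ext = 1.0;
  // aim for a few triangles per cell
  double cell = ext / std::max(4.0, std::cbrt((double)nf));
  g.cell = cell;
  for (int k = 0; k < 3; ++k) {
    g.origin[k] = lo[k] - 0.5 * cell;
    g.n[k] = std::max(1, (int)std::ceil((hi[k] - g.origin[k]) / cell) + 1);
  }
  g.bins.resize((size_t)g.n[0] * g.n[1] * g.n[2]);
  for (int f = 0; f < nf; ++f) {
    double tlo[3], thi[3];
    for (int k = 0; k < 3; ++k) { tlo[k] = R_PosInf; thi[k] = R_NegInf; }
    for (int c = 0; c < 3; ++c) {
      int vi = F(f, c) - 1;
      for (int k = 0; k < 3; ++k) {
        double x = V(vi, k);
        if (x < tlo[k]) tlo[k] = x;
        if (x > thi[k]) thi[k] = x;
      }
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = std::max(0, (int)std::floor((tlo[k] - g.origin[k]) / cell));
      i1[k] = std::min(g.n[k] - 1, (int)std::floor((thi[k] - g.origin[k]) / cell));
    }
    for (int i = i0[0]; i <= i1[0]; ++i)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int k = i0[2]; k <= i1[2]; ++k)
          g.bins[g.idx(i, j, k)].push_back(f);
  }

  NumericVector dist(nq);
  NumericMatrix cp(nq, 3);
  IntegerVector face(nq);
  std::vector<int> stamp((size_t)nf, -1);

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      int c = (int)std::floor((p[k] - g.origin[k]) / cell);
      ci[k] = std::min(std::max(c, 0), g.n[k] - 1);
    }
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    int maxn = std::max(g.n[0], std::max(g.n[1], g.n[2]));
    for (int ring = 0; ring <= maxn; ++ring) {
      // lower bound on distance to any cell in this ring
      if (bestf >= 0) {
        double lb = (ring - 1) * cell;
        if (lb > 0 && lb * lb > best) break;
      }
      bool any_cell = false;
      int i0 = ci[0] - ring, i1 = ci[0] + ring;
      int j0 = ci[1] - ring, j1 = ci[1] + ring;
      int k0 = ci[2] - ring, k1 = ci[2] + ring;
      for (int i = i0; i <= i1; ++i) {
        if (i < 0 || i >= g.n[0]) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= g.n[1]) continue;
          for (int k = k0; k <= k1; ++k) {
            if (k < 0 || k >= g.n[2]) continue;
            // only shell of the ring
            if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1)
              continue;
            any_cell = true;
            const std::vector<int> &bin = g.bins[g.idx(i, j, k)];
            for (size_t b = 0; b < bin.size(); ++b) {
              int f = bin[b];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              const double *a = &V(F(f, 0) - 1, 0);
              // NumericMatrix is column-major; need explicit copies
              double av[3] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
              double bv[3] = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
              double cv[3] = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
              (void)a;
              double pt[3];
              closest_on_tri(p, av, bv, cv, pt);
              double d2 = 0;
              for (int kk = 0; kk < 3; ++kk) {
                double d = p[kk] - pt[kk];
                d2 += d * d;
              }
              if (d2 < best) {
                best = d2;
                bestf = f;
                for (int kk = 0; kk < 3; ++kk) bestpt[kk] = pt[kk];
              }
            }
          }
        }
      }
      if (!any_cell && bestf >= 0) break;
      (void)any_cell;
    }
    dist[q] = std::sqrt(best);
    face[q] = bestf + 1;
    for (int kk = 0; kk < 3; ++kk) cp(q, kk) = bestpt[kk];
  }
  return List::create(_["distance"] = dist, _["point"] = cp, _["face"] = face);
}
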