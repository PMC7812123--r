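// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Per-vertex principal curvatures, principal directions and extremality
// coefficients from a local cubic height-field fit over a geodesic-like
// neighbourhood (edge-path Dijkstra within `radius`).
//
// Sign convention: surfaces convex with respect to the outward normal have
// positive curvature (a sphere with outward normals has k = +1/r).
// Extremality e_i is the directional derivative of principal curvature k_i
// along its own principal direction d_i, taken from the cubic terms.
// [[Rcpp::export]]
List cpp_curvature(NumericMatrix V, IntegerMatrix F, NumericMatrix normals,
                   double radius, int min_neighbors) {
  const int nv = V.nrow(), nf = F.nrow();
  // adjacency
  std::vector<std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }

  NumericVector kmax(nv), kmin(nv), emax(nv), emin(nv);
  NumericMatrix dmax(nv, 3), dmin(nv, 3);

  std::vector<double> dist(nv, R_PosInf);
  std::vector<int> touched;
  typedef std::pair<double, int> QE;

  arma::vec beta(9);
  for (int v0 = 0; v0 < nv; ++v0) {
    // local Dijkstra by cumulative edge length
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    touched.clear();
    dist[v0] = 0.0;
    touched.push_back(v0);
    pq.push(QE(0.0, v0));
    std::vector<int> nbrs;
    double rad = radius;
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int v = top.second;
      if (top.first > dist[v]) continue;
      if (top.first <= rad) nbrs.push_back(v);
      if (top.first > rad) continue;
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int w = adj[v][i];
        double dx = V(v, 0) - V(w, 0), dy = V(v, 1) - V(w, 1),
               dz = V(v, 2) - V(w, 2);
        double nd = top.first + std::sqrt(dx * dx + dy * dy + dz * dz);
        if (nd < dist[w] && nd <= rad * 2.5) {
          if (!std::isfinite(dist[w])) touched.push_back(w);
          dist[w] = nd;
          pq.push(QE(nd, w));
        }
      }
    }
    // grow by hops if too few neighbours
    if ((int)nbrs.size() < min_neighbors) {
      std::vector<int> frontier = nbrs;
      std::vector<char> in(nv, 0);
      for (size_t i = 0; i < nbrs.size(); ++i) in[nbrs[i]] = 1;
      while ((int)nbrs.size() < min_neighbors && !frontier.empty()) {
        std::vector<int> next;
        for (size_t i = 0; i < frontier.size(); ++i) {
          int v = frontier[i];
          for (size_t j = 0; j < adj[v].size(); ++j) {
            int w = adj[v][j];
            if (!in[w]) { in[w] = 1; nbrs.push_back(w); next.push_back(w); }
          }
        }
        frontier.swap(next);
      }
    }
    for (size_t i = 0; i < touched.size(); ++i) dist[touched[i]] = R_PosInf;
    if ((int)nbrs.size() < 6)
      stop("vertex %d has fewer than 6 usable neighbours", v0 + 1);

    // local frame: z along the outward vertex normal
    arma::vec3 n;
    n[0] = normals(v0, 0); n[1] = normals(v0, 1); n[2] = normals(v0, 2);
    n /= arma::norm(n);
    arma::vec3 a = std::fabs(n[0]) < 0.9 ? arma::vec3{1, 0, 0}
                                         : arma::vec3{0, 1, 0};
    arma::vec3 e1 = arma::normalise(a - arma::dot(a, n) * n);
    arma::vec3 e2 = arma::cross(n, e1);

    const int m = (int)nbrs.size();
    arma::mat X(m, 9);
    arma::vec h(m);
    for (int i = 0; i < m; ++i) {
      arma::vec3 d;
      d[0] = V(nbrs[i], 0) - V(v0, 0);
      d[1] = V(nbrs[i], 1) - V(v0, 1);
      d[2] = V(nbrs[i], 2) - V(v0, 2);
      double x = arma::dot(d, e1), y = arma::dot(d, e2);
      h[i] = arma::dot(d, n);
      X(i, 0) = x;           X(i, 1) = y;
      X(i, 2) = 0.5 * x * x; X(i, 3) = x * y; X(i, 4) = 0.5 * y * y;
      X(i, 5) = x * x * x;   X(i, 6) = x * x * y;
      X(i, 7) = x * y * y;   X(i, 8) = y * y * y;
    }
    arma::mat XtX = X.t() * X;
    XtX.diag() += 1e-10 * arma::trace(XtX) / 9.0;
    bool ok = arma::solve(beta, XtX, X.t() * h, arma::solve_opts::likely_sympd);
    if (!ok) stop("curvature fit failed at vertex %d", v0 + 1);

    double p = beta[0], q = beta[1];
    double W = std::sqrt(1.0 + p * p + q * q);
    // first fundamental form and second fundamental form of the height field
    double E = 1 + p * p, Ff = p * q, G = 1 + q * q;
    double L = beta[2] / W, M = beta[3] / W, N = beta[4] / W;
    // shape operator S = I^{-1} II (in the graph convention); our sign
    // convention flips it so convex-outward is positive
    double det = E * G - Ff * Ff;
    double s11 = (G * L - Ff * M) / det, s12 = (G * M - Ff * N) / det;
    double s21 = (E * M - Ff * L) / det, s22 = (E * N - Ff * M) / det;
    double tr = s11 + s22, dt = s11 * s22 - s12 * s21;
    double disc = std::sqrt(std::max(0.0, 0.25 * tr * tr - dt));
    double kg1 = 0.5 * tr + disc, kg2 = 0.5 * tr - disc;  // graph convention
    // principal directions in chart coords (eigenvectors of S)
    auto eigvec = [&](double kg, double *out) {
      double a11 = s11 - kg, a12 = s12, a21 = s21, a22 = s22 - kg;
      double vx, vy;
      if (std::fabs(a11) + std::fabs(a12) > std::fabs(a21) + std::fabs(a22)) {
        vx = -a12; vy = a11;
      } else {
        vx = -a22; vy = a21;
      }
      double nn = std::sqrt(vx * vx + vy * vy);
      if (nn < 1e-14) { vx = 1; vy = 0; nn = 1; }
      out[0] = vx / nn; out[1] = vy / nn;
    };
    double u1[2], u2[2];
    if (disc < 1e-12 * (1.0 + std::fabs(tr))) {
      u1[0] = 1; u1[1] = 0; u2[0] = 0; u2[1] = 1;  // umbilic
    } else {
      eigvec(kg1, u1);
      eigvec(kg2, u2);
    }
    // flip to our convention: k = -k_graph, so kmax_ours comes from kg2
    double k_max = -kg2, k_min = -kg1;
    double *um = u2, *un = u1;  // chart dirs for kmax/kmin

    // extremality from cubic terms: e = -D^3 h(d,d,d)
    double c30 = beta[5], c21 = beta[6], c12 = beta[7], c03 = beta[8];
    auto extrem = [&](const double *u) {
      double a1 = u[0], b1 = u[1];
      return -6.0 * (c30 * a1 * a1 * a1 + c21 * a1 * a1 * b1 +
                     c12 * a1 * b1 * b1 + c03 * b1 * b1 * b1);
    };
    kmax[v0] = k_max; kmin[v0] = k_min;
    emax[v0] = extrem(um); emin[v0] = extrem(un);
    // lift chart directions to 3D tangent vectors, orthogonal to the normal
    auto lift = [&](const double *u, NumericMatrix &D) {
      arma::vec3 t = u[0] * (e1 + p * n) + u[1] * (e2 + q * n);
      t -= arma::dot(t, n) * n;
      double nn = arma::norm(t);
      if (nn < 1e-14) { t = e1; nn = 1.0; }
      t /= nn;
      D(v0, 0) = t[0]; D(v0, 1) = t[1]; D(v0, 2) = t[2];
    };
    lift(um, dmax);
    lift(un, dmin);
  }
  return List::create(_["kmax"] = kmax, _["kmin"] = kmin,
                      _["dmax"] = dmax, _["dmin"] = dmin,
                      _["emax"] = emax, _["emin"] = emin);
}
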