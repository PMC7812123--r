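#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shortest-edge midpoint collapse decimation of a closed triangle mesh down to
// an exact face count. Each valid collapse of an interior edge removes exactly
// two faces; collapses are rejected when they would break the manifold link
// condition or flip a face normal.

namespace {

struct Entry {
  double len;
  int u, v;
  bool operator>(const Entry &o) const { return len > o.len; }
};

struct Mesh {
  std::vector<double> V;           // 3 * nv
  std::vector<int> F;              // 3 * nf
  std::vector<char> valive, falive;
  std::vector<std::vector<int> > vfaces;  // incident alive faces per vertex

  double *pos(int v) { return &V[3 * (size_t)v]; }
  int fv(int f, int c) const { return F[3 * (size_t)f + c]; }
  void set_fv(int f, int c, int v) { F[3 * (size_t)f + c] = v; }

  double elen2(int a, int b) {
    double *pa = pos(a), *pb = pos(b);
    double d0 = pa[0] - pb[0], d1 = pa[1] - pb[1], d2 = pa[2] - pb[2];
    return d0 * d0 + d1 * d1 + d2 * d2;
  }

  void face_normal(int f, const double *mu, int uidx, double *n) {
    // normal of face f, with vertex uidx (if present) evaluated at mu
    double p[3][3];
    for (int c = 0; c < 3; ++c) {
      int v = fv(f, c);
      const double *src = (v == uidx && mu) ? mu : pos(v);
      for (int k = 0; k < 3; ++k) p[c][k] = src[k];
    }
    double e1[3] = {p[1][0] - p[0][0], p[1][1] - p[0][1], p[1][2] - p[0][2]};
    double e2[3] = {p[2][0] - p[0][0], p[2][1] - p[0][1], p[2][2] - p[0][2]};
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
  }

  void vertex_neighbors(int v, std::vector<int> &out) {
    out.clear();
    for (size_t i = 0; i < vfaces[v].size(); ++i) {
      int f = vfaces[v][i];
      if (!falive[f]) continue;
      for (int c = 0; c < 3; ++c) {
        int w = fv(f, c);
        if (w != v) out.push_back(w);
      }
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }

  void prune_vfaces(int v) {
    std::vector<int> &fs = vfaces[v];
    size_t j = 0;
    for (size_t i = 0; i < fs.size(); ++i)
      if (falive[fs[i]]) fs[j++] = fs[i];
    fs.resize(j);
    std::sort(fs.begin(), fs.end());
    fs.erase(std::unique(fs.begin(), fs.end()), fs.end());
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  Mesh m;
  const int nv = Vin.nrow(), nf0 = Fin.nrow();
  m.V.resize(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) m.V[3 * (size_t)i + k] = Vin(i, k);
  m.F.resize(3 * (size_t)nf0);
  for (int f = 0; f < nf0; ++f)
    for (int c = 0; c < 3; ++c) m.F[3 * (size_t)f + c] = Fin(f, c) - 1;
  m.valive.assign(nv, 1);
  m.falive.assign(nf0, 1);
  m.vfaces.resize(nv);
  for (int f = 0; f < nf0; ++f)
    for (int c = 0; c < 3; ++c) m.vfaces[m.fv(f, c)].push_back(f);

  int nf_alive = nf0;
  if (target_faces >= nf0)
    stop("target_faces must be below the current face count");
  if (((nf0 - target_faces) % 2) != 0)
    stop("cannot reach target_faces exactly: face-count difference is odd");

  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry> > pq;
  for (int f = 0; f < nf0; ++f)
    for (int c = 0; c < 3; ++c) {
      int a = m.fv(f, c), b = m.fv(f, (c + 1) % 3);
      if (a < b) pq.push(Entry{std::sqrt(m.elen2(a, b)), a, b});
    }

  std::vector<int> nu, nv_, common, shared_faces, affected;
  int relax_pass = 0;
  bool relax_flip = false;

  while (nf_alive > target_faces) {
    if (pq.empty()) {
      // rebuild queue from scratch; after one clean rebuild, relax flip check
      if (relax_pass >= 2)
        stop("decimation stalled before reaching target face count");
      ++relax_pass;
      relax_flip = relax_pass >= 2;
      for (int v = 0; v < nv; ++v) {
        if (!m.valive[v]) continue;
        m.prune_vfaces(v);
        m.vertex_neighbors(v, nu);
        for (size_t i = 0; i < nu.size(); ++i)
          if (v < nu[i]) pq.push(Entry{std::sqrt(m.elen2(v, nu[i])), v, nu[i]});
      }
      if (pq.empty()) stop("no collapsible edges remain");
      continue;
    }
    Entry e = pq.top();
    pq.pop();
    int u = e.u, v = e.v;
    if (!m.valive[u] || !m.valive[v]) continue;
    double cur = std::sqrt(m.elen2(u, v));
    if (std::fabs(cur - e.len) > 1e-12 * (1.0 + cur)) continue;  // stale
    // shared faces
    shared_faces.clear();
    for (size_t i = 0; i < m.vfaces[u].size(); ++i) {
      int f = m.vfaces[u][i];
      if (!m.falive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (m.fv(f, c) == v) { shared_faces.push_back(f); break; }
    }
    if (shared_faces.size() != 2) continue;  // non-interior or stale
    // link condition: common neighbors must be exactly the 2 opposite verts
    m.vertex_neighbors(u, nu);
    m.vertex_neighbors(v, nv_);
    common.clear();
    std::set_intersection(nu.begin(), nu.end(), nv_.begin(), nv_.end(),
                          std::back_inserter(common));
    if (common.size() != 2) continue;
    // candidate midpoint
    double mid[3];
    for (int k = 0; k < 3; ++k) mid[k] = 0.5 * (m.pos(u)[k] + m.pos(v)[k]);
    // collect affected surviving faces
    affected.clear();
    for (int side = 0; side < 2; ++side) {
      int w = side == 0 ? u : v;
      for (size_t i = 0; i < m.vfaces[w].size(); ++i) {
        int f = m.vfaces[w][i];
        if (!m.falive[f]) continue;
        if (f == shared_faces[0] || f == shared_faces[1]) continue;
        affected.push_back(f);
      }
    }
    std::sort(affected.begin(), affected.end());
    affected.erase(std::unique(affected.begin(), affected.end()),
                   affected.end());
    if (!relax_flip) {
      bool bad = false;
      for (size_t i = 0; i < affected.size() && !bad; ++i) {
        int f = affected[i];
        double n0[3], n1[3];
        m.face_normal(f, NULL, -1, n0);
        // after collapse both u and v live at mid; evaluate with a temp swap
        int orig[3] = {m.fv(f, 0), m.fv(f, 1), m.fv(f, 2)};
        for (int c = 0; c < 3; ++c)
          if (m.fv(f, c) == v) m.set_fv(f, c, u);
        m.face_normal(f, mid, u, n1);
        for (int c = 0; c < 3; ++c) m.set_fv(f, c, orig[c]);
        double dot = n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2];
        double a1 = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
        double a0 = std::sqrt(n0[0] * n0[0] + n0[1] * n0[1] + n0[2] * n0[2]);
        if (dot <= 1e-14 || a1 < 1e-10 * (1.0 + a0)) bad = true;
      }
      if (bad) continue;
    }
    // apply collapse: v merges into u at midpoint
    for (int k = 0; k < 3; ++k) m.pos(u)[k] = mid[k];
    m.falive[shared_faces[0]] = 0;
    m.falive[shared_faces[1]] = 0;
    nf_alive -= 2;
    for (size_t i = 0; i < m.vfaces[v].size(); ++i) {
      int f = m.vfaces[v][i];
      if (!m.falive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (m.fv(f, c) == v) m.set_fv(f, c, u);
      m.vfaces[u].push_back(f);
    }
    m.valive[v] = 0;
    m.vfaces[v].clear();
    m.prune_vfaces(u);
    // refresh edge entries around u
    m.vertex_neighbors(u, nu);
    for (size_t i = 0; i < nu.size(); ++i) {
      int w = nu[i];
      int a = std::min(u, w), b = std::max(u, w);
      pq.push(Entry{std::sqrt(m.elen2(a, b)), a, b});
    }
  }

  // compact, keeping only vertices referenced by surviving faces
  std::vector<char> used(nv, 0);
  for (int f = 0; f < nf0; ++f)
    if (m.falive[f])
      for (int c = 0; c < 3; ++c) used[m.fv(f, c)] = 1;
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int v = 0; v < nv; ++v)
    if (used[v]) vmap[v] = nvo++;
  NumericMatrix Vout(nvo, 3);
  for (int v = 0; v < nv; ++v)
    if (vmap[v] >= 0)
      for (int k = 0; k < 3; ++k) Vout(vmap[v], k) = m.pos(v)[k];
  IntegerMatrix Fout(nf_alive, 3);
  int fo = 0;
  for (int f = 0; f < nf0; ++f) {
    if (!m.falive[f]) continue;
    for (int c = 0; c < 3; ++c) Fout(fo, c) = vmap[m.fv(f, c)] + 1;
    ++fo;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
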