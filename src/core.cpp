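// Compiled kernels: 3D connected components, marching-tetrahedra isosurface,
// ray-cast point-in-surface tests, neo-Hookean TLED force assembly and
// dynamic-relaxation solver, and barycentric label warping.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline double det3(const double M[3][3]) {
  return M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
         M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
         M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
}

static inline bool inv3(const double M[3][3], double Mi[3][3]) {
  double d = det3(M);
  if (d == 0.0) return false;
  double id = 1.0 / d;
  Mi[0][0] =  (M[1][1] * M[2][2] - M[1][2] * M[2][1]) * id;
  Mi[0][1] = -(M[0][1] * M[2][2] - M[0][2] * M[2][1]) * id;
  Mi[0][2] =  (M[0][1] * M[1][2] - M[0][2] * M[1][1]) * id;
  Mi[1][0] = -(M[1][0] * M[2][2] - M[1][2] * M[2][0]) * id;
  Mi[1][1] =  (M[0][0] * M[2][2] - M[0][2] * M[2][0]) * id;
  Mi[1][2] = -(M[0][0] * M[1][2] - M[0][2] * M[1][0]) * id;
  Mi[2][0] =  (M[1][0] * M[2][1] - M[1][1] * M[2][0]) * id;
  Mi[2][1] = -(M[0][0] * M[2][1] - M[0][1] * M[2][0]) * id;
  Mi[2][2] =  (M[0][0] * M[1][1] - M[0][1] * M[1][0]) * id;
  return true;
}

// ---------------------------------------------------------------------------
// Largest 6-connected foreground component of a 3D logical mask.
// [[Rcpp::export]]
LogicalVector largest_component_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = ncomp;
          stack.push_back(w);
        }
      }
    }
    if (size > best_size) { best_size = size; best_lab = ncomp; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (lab[s] == best_lab && best_lab > 0);
  out.attr("n_components") = ncomp;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over the Kuhn 6-tet decomposition of each grid cell.
// Vertices are deduplicated by global grid edge, so the surface is watertight
// and consistently oriented (normals point away from the field > level side).

struct MTState {
  std::map<std::pair<int64_t, int64_t>, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> t0, t1, t2;
};

static int mt_edge_vertex(MTState &st, int64_t ga, int64_t gb,
                          const double *pa, const double *pb,
                          double fa, double fb, double level) {
  if (ga > gb) { std::swap(ga, gb); std::swap(pa, pb); std::swap(fa, fb); }
  auto key = std::make_pair(ga, gb);
  auto it = st.edge_vert.find(key);
  if (it != st.edge_vert.end()) return it->second;
  double t = (level - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)st.vx.size() - 1;
  st.edge_vert[key] = id;
  return id;
}

static void mt_emit(MTState &st, int a, int b, int c, const double *away,
                    bool toward) {
  // orient so that the normal points along (toward ? +away : -away) direction
  double e1[3] = {st.vx[b] - st.vx[a], st.vy[b] - st.vy[a], st.vz[b] - st.vz[a]};
  double e2[3] = {st.vx[c] - st.vx[a], st.vy[c] - st.vy[a], st.vz[c] - st.vz[a]};
  double nrm[3] = {e1[1] * e2[2] - e1[2] * e2[1], e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
  double cx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0 - away[0];
  double cy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0 - away[1];
  double cz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0 - away[2];
  double dot = nrm[0] * cx + nrm[1] * cy + nrm[2] * cz;
  if ((toward && dot < 0) || (!toward && dot > 0)) std::swap(b, c);
  st.t0.push_back(a); st.t1.push_back(b); st.t2.push_back(c);
}

// [[Rcpp::export]]
List marching_tets_cpp(NumericVector field, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MTState st;
  // Kuhn tets: {0, a, a|b, 7} for permutations (a,b,c) of axis bits (1,2,4)
  const int kuhn[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                          {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double fv[8], pv[8][3];
  int64_t gid[8];
  const double eps = 1e-9 * (1.0 + std::abs(level));
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          int64_t g = ii + (int64_t)nx * (jj + (int64_t)ny * kk);
          gid[c] = g;
          double f = field[g];
          if (f == level) f += eps;  // avoid on-surface degeneracies
          fv[c] = f;
          pv[c][0] = origin[0] + ii * spacing[0];
          pv[c][1] = origin[1] + jj * spacing[1];
          pv[c][2] = origin[2] + kk * spacing[2];
          if (f > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = kuhn[t];
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (fv[T[v]] > level) ins[nin++] = T[v]; else outs[nout++] = T[v];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int *oth = (nin == 1) ? outs : ins;
            int e[3];
            for (int q = 0; q < 3; ++q)
              e[q] = mt_edge_vertex(st, gid[apex], gid[oth[q]], pv[apex],
                                    pv[oth[q]], fv[apex], fv[oth[q]], level);
            // normal must point away from the inside: away from apex when the
            // apex is the inside vertex, toward it when the apex is outside
            mt_emit(st, e[0], e[1], e[2], pv[apex], nin == 1);
          } else {  // 2-2 case: quad
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eAC = mt_edge_vertex(st, gid[A], gid[C], pv[A], pv[C], fv[A], fv[C], level);
            int eAD = mt_edge_vertex(st, gid[A], gid[D], pv[A], pv[D], fv[A], fv[D], level);
            int eBD = mt_edge_vertex(st, gid[B], gid[D], pv[B], pv[D], fv[B], fv[D], level);
            int eBC = mt_edge_vertex(st, gid[B], gid[C], pv[B], pv[C], fv[B], fv[C], level);
            double mid_in[3];  // midpoint of inside edge: normals point away
            for (int q = 0; q < 3; ++q) mid_in[q] = 0.5 * (pv[A][q] + pv[B][q]);
            mt_emit(st, eAC, eAD, eBD, mid_in, true);
            mt_emit(st, eAC, eBD, eBC, mid_in, true);
          }
        }
      }
    }
  }
  int nv = (int)st.vx.size(), nt = (int)st.t0.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = st.vx[v]; verts(v, 1) = st.vy[v]; verts(v, 2) = st.vz[v];
  }
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t) {
    tris(t, 0) = st.t0[t] + 1; tris(t, 1) = st.t1[t] + 1; tris(t, 2) = st.t2[t] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = tris);
}

// ---------------------------------------------------------------------------
// Ray-casting point-in-closed-surface test with degenerate-hit retries.

static int ray_hits_bucket(const NumericMatrix &V, const IntegerMatrix &F,
                           const std::vector<int> &cand, const double *o,
                           const double *d, bool &degenerate) {
  int hits = 0;
  degenerate = false;
  for (size_t c = 0; c < cand.size(); ++c) {
    const int t = cand[c];
    const int a = F(t, 0) - 1, b = F(t, 1) - 1, cc = F(t, 2) - 1;
    double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
    for (int q = 0; q < 3; ++q) {
      e1[q] = V(b, q) - V(a, q);
      e2[q] = V(cc, q) - V(a, q);
    }
    pvec[0] = d[1] * e2[2] - d[2] * e2[1];
    pvec[1] = d[2] * e2[0] - d[0] * e2[2];
    pvec[2] = d[0] * e2[1] - d[1] * e2[0];
    double det = e1[0] * pvec[0] + e1[1] * pvec[1] + e1[2] * pvec[2];
    if (std::abs(det) < 1e-14) continue;
    double inv = 1.0 / det;
    for (int q = 0; q < 3; ++q) tvec[q] = o[q] - V(a, q);
    double u = (tvec[0] * pvec[0] + tvec[1] * pvec[1] + tvec[2] * pvec[2]) * inv;
    if (u < -1e-10 || u > 1 + 1e-10) continue;
    qvec[0] = tvec[1] * e1[2] - tvec[2] * e1[1];
    qvec[1] = tvec[2] * e1[0] - tvec[0] * e1[2];
    qvec[2] = tvec[0] * e1[1] - tvec[1] * e1[0];
    double v = (d[0] * qvec[0] + d[1] * qvec[1] + d[2] * qvec[2]) * inv;
    if (v < -1e-10 || u + v > 1 + 1e-10) continue;
    double tt = (e2[0] * qvec[0] + e2[1] * qvec[1] + e2[2] * qvec[2]) * inv;
    if (tt <= 1e-12) continue;
    if (u < 1e-9 || v < 1e-9 || u + v > 1 - 1e-9) { degenerate = true; return -1; }
    ++hits;
  }
  return hits;
}

// Point-in-closed-surface by parity of crossings along near-+x rays, with a
// 2D (y, z) bucket grid over triangle bounding boxes and tilted-direction
// retries on edge-grazing hits.
// [[Rcpp::export]]
LogicalVector points_in_surface_cpp(NumericMatrix verts, IntegerMatrix tris,
                                    NumericMatrix pts) {
  const int np = pts.nrow(), nt = tris.nrow(), nv = verts.nrow();
  LogicalVector out(np);
  if (nt == 0) return out;
  double lo[3], hi[3];
  for (int q = 0; q < 3; ++q) { lo[q] = R_PosInf; hi[q] = R_NegInf; }
  for (int v = 0; v < nv; ++v)
    for (int q = 0; q < 3; ++q) {
      lo[q] = std::min(lo[q], verts(v, q));
      hi[q] = std::max(hi[q], verts(v, q));
    }
  double span_y = std::max(hi[1] - lo[1], 1e-9);
  double span_z = std::max(hi[2] - lo[2], 1e-9);
  int nb = std::max(1, (int)std::sqrt((double)nt / 4.0));
  int by = nb, bz = nb;
  double cy = span_y / by, cz = span_z / bz;
  std::vector<std::vector<int>> bucket((size_t)by * bz);
  for (int t = 0; t < nt; ++t) {
    double ylo = R_PosInf, yhi = R_NegInf, zlo = R_PosInf, zhi = R_NegInf;
    for (int v = 0; v < 3; ++v) {
      int a = tris(t, v) - 1;
      ylo = std::min(ylo, verts(a, 1)); yhi = std::max(yhi, verts(a, 1));
      zlo = std::min(zlo, verts(a, 2)); zhi = std::max(zhi, verts(a, 2));
    }
    // small margin covers the tilted retry directions
    int j0 = std::max(0, (int)((ylo - lo[1] - 1e-6) / cy));
    int j1 = std::min(by - 1, (int)((yhi - lo[1] + 1e-6) / cy));
    int k0 = std::max(0, (int)((zlo - lo[2] - 1e-6) / cz));
    int k1 = std::min(bz - 1, (int)((zhi - lo[2] + 1e-6) / cz));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bucket[j + (size_t)by * k].push_back(t);
  }
  static const double tilts[5][2] = {{0.0, 0.0},
                                     {1.1e-4, 2.3e-4},
                                     {-2.9e-4, 1.7e-4},
                                     {3.1e-4, -1.3e-4},
                                     {-1.9e-4, -2.7e-4}};
  for (int p = 0; p < np; ++p) {
    double o[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    bool outside_box = false;
    for (int q = 0; q < 3; ++q)
      if (o[q] < lo[q] || o[q] > hi[q]) outside_box = true;
    if (outside_box) { out[p] = false; continue; }
    int j = std::min(by - 1, std::max(0, (int)((o[1] - lo[1]) / cy)));
    int k = std::min(bz - 1, std::max(0, (int)((o[2] - lo[2]) / cz)));
    const std::vector<int> &cand = bucket[j + (size_t)by * k];
    int hits = -1;
    for (int attempt = 0; attempt < 5 && hits < 0; ++attempt) {
      double d[3] = {1.0, tilts[attempt][0], tilts[attempt][1]};
      bool degen;
      hits = ray_hits_bucket(verts, tris, cand, o, d, degen);
      if (degen) hits = -1;
    }
    out[p] = (hits > 0) && (hits % 2 == 1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Neo-Hookean second Piola-Kirchhoff stress from F (shared by force assembly):
// Psi = mu/2 (J^{-2/3} I1 - 3) + K/2 (J - 1)^2
static void nh_first_piola(const double F[3][3], double mu, double K,
                           double P[3][3], double *Jout) {
  double J = det3(F);
  *Jout = J;
  if (J <= 0) return;
  double C[3][3], Ci[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      C[a][b] = 0;
      for (int q = 0; q < 3; ++q) C[a][b] += F[q][a] * F[q][b];
    }
  inv3(C, Ci);
  double I1 = C[0][0] + C[1][1] + C[2][2];
  double Jm23 = 1.0 / std::cbrt(J * J);   // J^(-2/3), much cheaper than pow
  double vol = K * J * (J - 1.0);
  double S[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      S[a][b] = mu * Jm23 * ((a == b ? 1.0 : 0.0) - I1 / 3.0 * Ci[a][b]) +
                vol * Ci[a][b];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      P[a][b] = 0;
      for (int q = 0; q < 3; ++q) P[a][b] += F[a][q] * S[q][b];
    }
}

struct ElemCache {
  std::vector<double> Bm;   // 9 per element: inverse reference edge matrix
  std::vector<double> V0;   // reference volume
  std::vector<int> nd;      // 4 per element: 0-based node ids
};

static bool build_cache(const NumericMatrix &X, const IntegerMatrix &tets,
                        ElemCache &ec, int *bad) {
  const int m = tets.nrow();
  ec.Bm.assign((size_t)m * 9, 0.0);
  ec.V0.assign(m, 0.0);
  ec.nd.assign((size_t)m * 4, 0);
  for (int e = 0; e < m; ++e) {
    int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
        n3 = tets(e, 3) - 1;
    ec.nd[(size_t)e * 4] = n0;
    ec.nd[(size_t)e * 4 + 1] = n1;
    ec.nd[(size_t)e * 4 + 2] = n2;
    ec.nd[(size_t)e * 4 + 3] = n3;
    double Dm[3][3], Bm[3][3];
    for (int q = 0; q < 3; ++q) {
      Dm[q][0] = X(n1, q) - X(n0, q);
      Dm[q][1] = X(n2, q) - X(n0, q);
      Dm[q][2] = X(n3, q) - X(n0, q);
    }
    double V = det3(Dm) / 6.0;
    if (V <= 0) { *bad = e + 1; return false; }
    inv3(Dm, Bm);
    ec.V0[e] = V;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) ec.Bm[(size_t)e * 9 + 3 * a + b] = Bm[a][b];
  }
  return true;
}

// internal elastic forces at current coords x; returns false on inversion
static bool forces_from(const NumericMatrix &X, const std::vector<double> &x,
                        const IntegerMatrix &tets, const ElemCache &ec,
                        const NumericVector &mu, const NumericVector &K,
                        std::vector<double> &f, double *minJ, int *bad) {
  const int n = X.nrow(), m = tets.nrow();
  std::fill(f.begin(), f.end(), 0.0);
  *minJ = R_PosInf;
  for (int e = 0; e < m; ++e) {
    const int *nd = &ec.nd[(size_t)e * 4];
    double Ds[3][3];
    for (int q = 0; q < 3; ++q) {
      Ds[q][0] = x[nd[1] + q * n] - x[nd[0] + q * n];
      Ds[q][1] = x[nd[2] + q * n] - x[nd[0] + q * n];
      Ds[q][2] = x[nd[3] + q * n] - x[nd[0] + q * n];
    }
    const double *Bm = &ec.Bm[(size_t)e * 9];
    double F[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        F[a][b] = 0;
        for (int q = 0; q < 3; ++q) F[a][b] += Ds[a][q] * Bm[3 * q + b];
      }
    double P[3][3], J;
    nh_first_piola(F, mu[e], K[e], P, &J);
    if (J <= 0) { *bad = e + 1; return false; }
    if (J < *minJ) *minJ = J;
    // H = -V0 * P * Bm^T ; columns are forces on nodes 1..3, node 0 balances
    double H[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        H[a][b] = 0;
        for (int q = 0; q < 3; ++q) H[a][b] -= ec.V0[e] * P[a][q] * Bm[3 * b + q];
      }
    for (int q = 0; q < 3; ++q) {
      f[nd[1] + q * n] += H[q][0];
      f[nd[2] + q * n] += H[q][1];
      f[nd[3] + q * n] += H[q][2];
      f[nd[0] + q * n] -= H[q][0] + H[q][1] + H[q][2];
    }
  }
  return true;
}

// [[Rcpp::export]]
List internal_forces_cpp(NumericMatrix X, NumericMatrix x, IntegerMatrix tets,
                         NumericVector mu, NumericVector K) {
  const int n = X.nrow();
  ElemCache ec;
  int bad = 0;
  if (!build_cache(X, tets, ec, &bad))
    return List::create(_["ok"] = false, _["bad_element"] = bad);
  std::vector<double> xc((size_t)n * 3), f((size_t)n * 3);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) xc[i + q * n] = x(i, q);
  double minJ;
  bool ok = forces_from(X, xc, tets, ec, mu, K, f, &minJ, &bad);
  NumericMatrix out(n, 3);
  if (ok)
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q) out(i, q) = f[i + q * n];
  return List::create(_["ok"] = ok, _["forces"] = out, _["min_J"] = minJ,
                      _["bad_element"] = bad);
}

// ---------------------------------------------------------------------------
// TLED dynamic relaxation: central-difference explicit integration with
// mass-proportional damping, gravity ramped over the first ramp_steps steps.
// All quantities SI (meters, kg, seconds, Newtons).
// [[Rcpp::export]]
List tled_solve_cpp(NumericMatrix X, IntegerMatrix tets, NumericVector mu,
                    NumericVector K, double rho, LogicalVector fixed,
                    NumericVector gravity, double load_factor, double dt,
                    double damping, double tol_v, double tol_f,
                    int max_steps, int ramp_steps, int check_every,
                    NumericMatrix x0) {
  const int n = X.nrow();
  ElemCache ec;
  int bad = 0;
  if (!build_cache(X, tets, ec, &bad))
    return List::create(_["ok"] = false, _["reason"] = "inverted_reference",
                        _["bad_element"] = bad);
  // lumped mass and gravity forces
  std::vector<double> mass(n, 0.0), fg((size_t)n * 3, 0.0);
  for (int e = 0; e < tets.nrow(); ++e) {
    double mq = rho * ec.V0[e] / 4.0;
    for (int v = 0; v < 4; ++v) {
      int nd = tets(e, v) - 1;
      mass[nd] += mq;
      for (int q = 0; q < 3; ++q)
        fg[nd + q * n] += mq * gravity[q] * load_factor;
    }
  }
  std::vector<double> x((size_t)n * 3), vel((size_t)n * 3, 0.0),
      f((size_t)n * 3);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) x[i + q * n] = x0(i, q);
  std::vector<double> resid_hist, ke_hist;
  bool converged = false;
  int step = 0;
  double max_resid = NA_REAL, max_v = NA_REAL, minJ = NA_REAL;
  const double cd = damping;
  for (step = 0; step < max_steps; ++step) {
    double ramp = ramp_steps > 0 ? std::min(1.0, (step + 1.0) / ramp_steps) : 1.0;
    if (!forces_from(X, x, tets, ec, mu, K, f, &minJ, &bad))
      return List::create(_["ok"] = false, _["reason"] = "element_inversion",
                          _["bad_element"] = bad, _["step"] = step,
                          _["resid_history"] = wrap(resid_hist));
    double a1 = 1.0 - cd * dt / 2.0, a2 = 1.0 / (1.0 + cd * dt / 2.0);
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) {
        for (int q = 0; q < 3; ++q) vel[i + q * n] = 0.0;
        continue;
      }
      for (int q = 0; q < 3; ++q) {
        double acc = (f[i + q * n] + ramp * fg[i + q * n]) / mass[i];
        vel[i + q * n] = a2 * (a1 * vel[i + q * n] + dt * acc);
        x[i + q * n] += dt * vel[i + q * n];
      }
    }
    if ((step + 1) % check_every == 0 && step + 1 >= ramp_steps) {
      max_v = 0.0;
      max_resid = 0.0;
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        double v2 = 0, r2 = 0;
        for (int q = 0; q < 3; ++q) {
          double vq = vel[i + q * n];
          v2 += vq * vq;
          if (!fixed[i]) {
            double rq = f[i + q * n] + fg[i + q * n];
            r2 += rq * rq;
          }
        }
        ke += 0.5 * mass[i] * v2;
        max_v = std::max(max_v, std::sqrt(v2));
        max_resid = std::max(max_resid, std::sqrt(r2));
      }
      resid_hist.push_back(max_resid);
      ke_hist.push_back(ke);
      if (max_v < tol_v && max_resid < tol_f) { converged = true; ++step; break; }
    }
  }
  NumericMatrix xout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) xout(i, q) = x[i + q * n];
  return List::create(_["ok"] = true, _["x"] = xout, _["converged"] = converged,
                      _["steps"] = step, _["max_resid"] = max_resid,
                      _["max_v"] = max_v, _["min_J"] = minJ,
                      _["resid_history"] = wrap(resid_hist),
                      _["ke_history"] = wrap(ke_hist));
}

// ---------------------------------------------------------------------------
// Warp a prone label volume into the supine configuration: for every voxel
// center of the output grid, find the containing supine tet, map to the prone
// configuration by barycentric interpolation, sample nearest-neighbor label.
// [[Rcpp::export]]
List warp_labels_cpp(NumericMatrix sup_nodes, NumericMatrix prone_nodes,
                     IntegerMatrix tets, IntegerVector labels,
                     IntegerVector dim, NumericVector spacing,
                     NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = tets.nrow();
  // per-tet inverse edge matrices in supine config + bucket grid over bbox
  std::vector<double> Ti((size_t)m * 9);
  std::vector<int> ok_tet(m, 1);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double avg_edge = 0.0;
  for (int e = 0; e < m; ++e) {
    int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
        n3 = tets(e, 3) - 1;
    double T[3][3], Tinv[3][3];
    for (int q = 0; q < 3; ++q) {
      T[q][0] = sup_nodes(n1, q) - sup_nodes(n0, q);
      T[q][1] = sup_nodes(n2, q) - sup_nodes(n0, q);
      T[q][2] = sup_nodes(n3, q) - sup_nodes(n0, q);
    }
    if (!inv3(T, Tinv)) { ok_tet[e] = 0; continue; }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) Ti[(size_t)e * 9 + 3 * a + b] = Tinv[a][b];
    for (int v = 0; v < 4; ++v) {
      int nd = tets(e, v) - 1;
      for (int q = 0; q < 3; ++q) {
        lo[q] = std::min(lo[q], sup_nodes(nd, q));
        hi[q] = std::max(hi[q], sup_nodes(nd, q));
      }
    }
    avg_edge += std::abs(det3(T));
  }
  avg_edge = std::cbrt(avg_edge / std::max(1, m));  // ~ element scale
  double cell = std::max(avg_edge, 1e-6);
  int bx = std::max(1, (int)((hi[0] - lo[0]) / cell) + 1);
  int by = std::max(1, (int)((hi[1] - lo[1]) / cell) + 1);
  int bz = std::max(1, (int)((hi[2] - lo[2]) / cell) + 1);
  std::vector<std::vector<int>> bucket((size_t)bx * by * bz);
  for (int e = 0; e < m; ++e) {
    if (!ok_tet[e]) continue;
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf},
           thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int v = 0; v < 4; ++v) {
      int nd = tets(e, v) - 1;
      for (int q = 0; q < 3; ++q) {
        tlo[q] = std::min(tlo[q], sup_nodes(nd, q));
        thi[q] = std::max(thi[q], sup_nodes(nd, q));
      }
    }
    int i0 = std::max(0, (int)((tlo[0] - lo[0]) / cell));
    int i1 = std::min(bx - 1, (int)((thi[0] - lo[0]) / cell));
    int j0 = std::max(0, (int)((tlo[1] - lo[1]) / cell));
    int j1 = std::min(by - 1, (int)((thi[1] - lo[1]) / cell));
    int k0 = std::max(0, (int)((tlo[2] - lo[2]) / cell));
    int k1 = std::min(bz - 1, (int)((thi[2] - lo[2]) / cell));
    for (int kk = k0; kk <= k1; ++kk)
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          bucket[ii + (size_t)bx * (jj + (size_t)by * kk)].push_back(e);
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t n_inside = 0;
  const double tol = -1e-8;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double p[3] = {origin[0] + i * spacing[0], origin[1] + j * spacing[1],
                       origin[2] + k * spacing[2]};
        R_xlen_t vox = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        out[vox] = 0;
        if (p[0] < lo[0] || p[0] > hi[0] || p[1] < lo[1] || p[1] > hi[1] ||
            p[2] < lo[2] || p[2] > hi[2])
          continue;
        int bi = std::min(bx - 1, std::max(0, (int)((p[0] - lo[0]) / cell)));
        int bj = std::min(by - 1, std::max(0, (int)((p[1] - lo[1]) / cell)));
        int bk = std::min(bz - 1, std::max(0, (int)((p[2] - lo[2]) / cell)));
        const std::vector<int> &cand =
            bucket[bi + (size_t)bx * (bj + (size_t)by * bk)];
        for (size_t ci = 0; ci < cand.size(); ++ci) {
          int e = cand[ci];
          int n0 = tets(e, 0) - 1;
          double r[3] = {p[0] - sup_nodes(n0, 0), p[1] - sup_nodes(n0, 1),
                         p[2] - sup_nodes(n0, 2)};
          const double *A = &Ti[(size_t)e * 9];
          double b1 = A[0] * r[0] + A[1] * r[1] + A[2] * r[2];
          double b2 = A[3] * r[0] + A[4] * r[1] + A[5] * r[2];
          double b3 = A[6] * r[0] + A[7] * r[1] + A[8] * r[2];
          double b0 = 1.0 - b1 - b2 - b3;
          if (b0 < tol || b1 < tol || b2 < tol || b3 < tol) continue;
          ++n_inside;
          double q[3];
          for (int a = 0; a < 3; ++a)
            q[a] = b0 * prone_nodes(tets(e, 0) - 1, a) +
                   b1 * prone_nodes(tets(e, 1) - 1, a) +
                   b2 * prone_nodes(tets(e, 2) - 1, a) +
                   b3 * prone_nodes(tets(e, 3) - 1, a);
          int vi = (int)std::lround((q[0] - origin[0]) / spacing[0]);
          int vj = (int)std::lround((q[1] - origin[1]) / spacing[1]);
          int vk = (int)std::lround((q[2] - origin[2]) / spacing[2]);
          int lab = 0;
          if (vi >= 0 && vi < nx && vj >= 0 && vj < ny && vk >= 0 && vk < nz)
            lab = labels[vi + (R_xlen_t)nx * (vj + (R_xlen_t)ny * vk)];
          if (lab == 0) {
            // the voxel is inside the deformed mesh, so its preimage should
            // be tissue: rounding near the mask boundary can land on
            // background; fall back to the first labeled 6-neighbor
            const int di[6] = {-1, 1, 0, 0, 0, 0};
            const int dj[6] = {0, 0, -1, 1, 0, 0};
            const int dk[6] = {0, 0, 0, 0, -1, 1};
            for (int q6 = 0; q6 < 6 && lab == 0; ++q6) {
              int ni = vi + di[q6], nj = vj + dj[q6], nk = vk + dk[q6];
              if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 ||
                  nk >= nz)
                continue;
              lab = labels[ni + (R_xlen_t)nx * (nj + (R_xlen_t)ny * nk)];
            }
          }
          out[vox] = lab;
          break;
        }
      }
  return List::create(_["labels"] = out, _["n_inside"] = (double)n_inside);
}
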