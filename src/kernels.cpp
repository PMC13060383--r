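// Low-level kernels for the charge-based boundary element method.
//
// Conventions: coordinates in meters, charge unknowns are rho/eps0 (V/m).
// A source triangle K with scaled charge density c_K contributes
//   potential  u(x) = |K| c_K / (4 pi |x - x_K|)          (point form)
//   field      E(x) = |K| c_K (x - x_K) / (4 pi |x-x_K|^3)
// in the centroid approximation; near-field routines integrate the constant
// density over the flat triangle analytically.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const double FOURPI = 4.0 * M_PI;

// ---------------------------------------------------------------------------
// direct (O(N M)) evaluation
// ---------------------------------------------------------------------------

// src: M x 3 source points, w: M weights (|K| * c_K), tgt: N x 3 targets,
// excl: N integers, 0-based index of a source to skip (or -1).
// [[Rcpp::export]]
List cb_direct_eval(NumericMatrix src, NumericVector w, NumericMatrix tgt,
                    IntegerVector excl, bool want_pot, bool want_field) {
  const int M = src.nrow(), N = tgt.nrow();
  NumericVector pot(want_pot ? N : 0);
  NumericMatrix field(want_field ? N : 0, 3);
  // contiguous per-coordinate copies keep the inner loop vectorizable
  std::vector<double> sx(M), sy(M), sz(M), ww(M);
  for (int j = 0; j < M; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); sz[j] = src(j, 2); ww[j] = w[j];
  }
  bool bad = false;
  for (int i = 0; i < N; ++i) {
    const double tx = tgt(i, 0), ty = tgt(i, 1), tz = tgt(i, 2);
    const int skip = (excl.size() == N) ? excl[i] : -1;
    double p = 0.0, fx = 0.0, fy = 0.0, fz = 0.0;
    // two clean ranges around the excluded source: no branch in the loop;
    // a coincident pair surfaces as a non-finite sum and is caught below
    for (int half = 0; half < 2; ++half) {
      const int j0 = (half == 0) ? 0 : ((skip >= 0 && skip < M) ? skip + 1 : M);
      const int j1 = (half == 0) ? ((skip >= 0 && skip < M) ? skip : M) : M;
      if (want_field) {
        for (int j = j0; j < j1; ++j) {
          const double dx = tx - sx[j], dy = ty - sy[j], dz = tz - sz[j];
          const double r2 = dx * dx + dy * dy + dz * dz;
          const double rinv = 1.0 / std::sqrt(r2);
          const double wr = ww[j] * rinv;
          p += wr;
          const double s = wr * rinv * rinv;
          fx += s * dx; fy += s * dy; fz += s * dz;
        }
      } else {
        for (int j = j0; j < j1; ++j) {
          const double dx = tx - sx[j], dy = ty - sy[j], dz = tz - sz[j];
          p += ww[j] / std::sqrt(dx * dx + dy * dy + dz * dz);
        }
      }
    }
    if (!std::isfinite(p) || (want_field && !(std::isfinite(fx) &&
        std::isfinite(fy) && std::isfinite(fz)))) bad = true;
    if (want_pot) pot[i] = p / FOURPI;
    if (want_field) {
      field(i, 0) = fx / FOURPI; field(i, 1) = fy / FOURPI; field(i, 2) = fz / FOURPI;
    }
  }
  if (bad) stop("coincident source and target point in direct evaluation");
  return List::create(_["potential"] = pot, _["field"] = field);
}

// ---------------------------------------------------------------------------
// analytic constant-density flat-triangle integrals (Wilton-style line form)
// ---------------------------------------------------------------------------

static inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// I = int_T 1/|x - y| dS(y) over flat triangle (A,B,C); grad = d I / d x.
static void tri_potential_grad(const double* A, const double* B, const double* C,
                               const double* x, double* I_out, double* grad_out) {
  double e1[3], e2[3], nrm[3];
  vsub(B, A, e1); vsub(C, A, e2); vcross(e1, e2, nrm);
  const double nn = vnorm(nrm);
  if (nn <= 0.0) { *I_out = 0.0; grad_out[0] = grad_out[1] = grad_out[2] = 0.0; return; }
  nrm[0] /= nn; nrm[1] /= nn; nrm[2] /= nn;
  double xa[3]; vsub(x, A, xa);
  const double h = vdot(xa, nrm);
  const double ah = std::fabs(h);
  // projection of x onto the triangle plane
  double p[3] = { x[0] - h * nrm[0], x[1] - h * nrm[1], x[2] - h * nrm[2] };

  const double* V[4] = { A, B, C, A };
  double I = 0.0, g[3] = {0.0, 0.0, 0.0}, beta_sum = 0.0;
  const double scale = std::sqrt(nn);  // ~ edge length scale
  const double tiny = 1e-14 * std::max(scale, 1e-300);

  for (int e = 0; e < 3; ++e) {
    const double* P = V[e];
    const double* Q = V[e + 1];
    double s[3]; vsub(Q, P, s);
    const double ls = vnorm(s);
    if (ls <= 0.0) continue;
    s[0] /= ls; s[1] /= ls; s[2] /= ls;
    double m[3]; vcross(s, nrm, m);  // in-plane outward normal of the edge
    double Pp[3], Qp[3]; vsub(P, p, Pp); vsub(Q, p, Qp);
    const double lm = vdot(Pp, s), lp = vdot(Qp, s);
    const double t0 = vdot(Pp, m);
    double dPm[3], dQm[3]; vsub(x, P, dPm); vsub(x, Q, dQm);
    const double Rm = vnorm(dPm), Rp = vnorm(dQm);
    const double R02 = t0 * t0 + h * h;
    if (R02 < tiny * tiny && ah < tiny) continue;  // observation on the edge line
    // ln((Rp + lp)/(Rm + lm)); the algebraically equal form
    // ln((Rm - lm)/(Rp - lp)) is better conditioned when lp + lm < 0
    double lg;
    if (lp + lm >= 0.0) {
      const double num = Rp + lp, den = Rm + lm;
      lg = (num > tiny && den > tiny) ? std::log(num / den) : 0.0;
    } else {
      const double num = Rm - lm, den = Rp - lp;
      lg = (num > tiny && den > tiny) ? std::log(num / den) : 0.0;
    }
    const double bp = std::atan2(t0 * lp, R02 + ah * Rp);
    const double bm = std::atan2(t0 * lm, R02 + ah * Rm);
    const double beta = bp - bm;
    beta_sum += beta;
    I += t0 * lg - ah * beta;
    g[0] -= m[0] * lg; g[1] -= m[1] * lg; g[2] -= m[2] * lg;
  }
  const double sgn = (h > 0.0) ? 1.0 : ((h < 0.0) ? -1.0 : 0.0);
  g[0] -= nrm[0] * sgn * beta_sum;
  g[1] -= nrm[1] * sgn * beta_sum;
  g[2] -= nrm[2] * sgn * beta_sum;
  *I_out = I;
  grad_out[0] = g[0]; grad_out[1] = g[1]; grad_out[2] = g[2];
}

// Exposed for testing: potential integral and gradient for one triangle.
// verts: 3 x 3 matrix (rows A, B, C); x: length-3 point.
// [[Rcpp::export]]
List cb_tri_integral(NumericMatrix verts, NumericVector x) {
  double A[3], B[3], C[3], xx[3], I, g[3];
  for (int k = 0; k < 3; ++k) {
    A[k] = verts(0, k); B[k] = verts(1, k); C[k] = verts(2, k); xx[k] = x[k];
  }
  tri_potential_grad(A, B, C, xx, &I, g);
  return List::create(_["I"] = I,
                      _["grad"] = NumericVector::create(g[0], g[1], g[2]));
}

// Per-pair near-field correction values for unit scaled charge on the source
// triangle: d_pot = I/(4pi) - |K|/(4pi d); d_field = -grad(I)/(4pi) - point field.
// Self pairs (target centroid == source centroid) get the analytic value alone
// for the potential and NA field (callers must not use field self terms).
// [[Rcpp::export]]
List cb_near_values(NumericMatrix V, IntegerMatrix F, NumericMatrix cent,
                    NumericVector area, NumericMatrix tgt,
                    IntegerMatrix pairs, IntegerVector tgt_src_index) {
  const int K = pairs.nrow();
  NumericVector dpot(K);
  NumericMatrix dfield(K, 3);
  for (int q = 0; q < K; ++q) {
    const int i = pairs(q, 0);  // 0-based target index
    const int j = pairs(q, 1);  // 0-based source triangle index
    double A[3], B[3], C[3], x[3], I, g[3];
    const int a = F(j, 0), b = F(j, 1), c = F(j, 2);
    for (int k = 0; k < 3; ++k) {
      A[k] = V(a, k); B[k] = V(b, k); C[k] = V(c, k); x[k] = tgt(i, k);
    }
    tri_potential_grad(A, B, C, x, &I, g);
    const bool self = (tgt_src_index.size() == tgt.nrow()) && (tgt_src_index[i] == j);
    if (self) {
      dpot[q] = I / FOURPI;  // point term was excluded for self
      dfield(q, 0) = NA_REAL; dfield(q, 1) = NA_REAL; dfield(q, 2) = NA_REAL;
      continue;
    }
    double dx = x[0] - cent(j, 0), dy = x[1] - cent(j, 1), dz = x[2] - cent(j, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double r = std::sqrt(r2);
    if (r <= 0.0) stop("coincident centroids in near pair (%d, %d)", i + 1, j + 1);
    dpot[q] = (I - area[j] / r) / FOURPI;
    const double s = area[j] / (r2 * r);
    dfield(q, 0) = (-g[0] - s * dx) / FOURPI;
    dfield(q, 1) = (-g[1] - s * dy) / FOURPI;
    dfield(q, 2) = (-g[2] - s * dz) / FOURPI;
  }
  return List::create(_["dpot"] = dpot, _["dfield"] = dfield);
}

// ---------------------------------------------------------------------------
// near-pair search on a uniform grid
// ---------------------------------------------------------------------------

// Pairs (target i, source j) with |tgt_i - cent_j| < factor * max(Lt_i, Ls_j).
// Lt may be a zero vector for point targets. Returns a 2-column 0-based matrix.
// [[Rcpp::export]]
IntegerMatrix cb_near_pairs(NumericMatrix tgt, NumericVector Lt,
                            NumericMatrix cent, NumericVector Ls,
                            double factor) {
  const int N = tgt.nrow(), M = cent.nrow();
  double maxL = 0.0;
  for (int j = 0; j < M; ++j) maxL = std::max(maxL, Ls[j]);
  for (int i = 0; i < N; ++i) maxL = std::max(maxL, Lt[i]);
  const double h = std::max(factor * maxL, 1e-12);
  // hash sources into grid cells of size h
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < 3; ++k) lo[k] = std::min(lo[k], cent(j, k));
  auto cellof = [&](double x, int k) {
    return (int)std::floor((x - lo[k]) / h);
  };
  auto mk = [](int a, int b, int c) {
    return ((int64_t)(a + 1048576) << 42) | ((int64_t)(b + 1048576) << 21) |
           (int64_t)(c + 1048576);
  };
  std::vector<std::pair<int64_t, int>> cells(M);
  for (int j = 0; j < M; ++j) {
    cells[j] = {mk(cellof(cent(j, 0), 0), cellof(cent(j, 1), 1), cellof(cent(j, 2), 2)), j};
  }
  std::sort(cells.begin(), cells.end());
  std::vector<int> out_i, out_j;
  for (int i = 0; i < N; ++i) {
    const double tx = tgt(i, 0), ty = tgt(i, 1), tz = tgt(i, 2);
    const int cx = cellof(tx, 0), cy = cellof(ty, 1), cz = cellof(tz, 2);
    for (int ax = cx - 1; ax <= cx + 1; ++ax)
      for (int ay = cy - 1; ay <= cy + 1; ++ay)
        for (int az = cz - 1; az <= cz + 1; ++az) {
          const int64_t kk = mk(ax, ay, az);
          auto itlo = std::lower_bound(cells.begin(), cells.end(),
                                       std::make_pair(kk, -1));
          for (auto it = itlo; it != cells.end() && it->first == kk; ++it) {
            const int j = it->second;
            const double dx = tx - cent(j, 0), dy = ty - cent(j, 1), dz = tz - cent(j, 2);
            const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (d < factor * std::max(Lt[i], Ls[j])) {
              out_i.push_back(i); out_j.push_back(j);
            }
          }
        }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t q = 0; q < out_i.size(); ++q) {
    out(q, 0) = out_i[q]; out(q, 1) = out_j[q];
  }
  return out;
}

// Sparse correction apply: out[i[q]] += v[q] * c[j[q]] (0-based indices).
// [[Rcpp::export]]
NumericVector cb_pair_apply(IntegerVector i, IntegerVector j, NumericVector v,
                            NumericVector c, int n) {
  NumericVector out(n);
  const int K = i.size();
  for (int q = 0; q < K; ++q) out[i[q]] += v[q] * c[j[q]];
  return out;
}

// ---------------------------------------------------------------------------
// k-nearest neighbors (brute force)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cb_knn(NumericMatrix query, NumericMatrix pts, int k) {
  const int N = query.nrow(), M = pts.nrow();
  if (k > M) stop("k (%d) exceeds the number of candidate points (%d)", k, M);
  IntegerMatrix out(N, k);
  std::vector<std::pair<double, int>> d(M);
  for (int i = 0; i < N; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < M; ++j) {
      const double dx = qx - pts(j, 0), dy = qy - pts(j, 1), dz = qz - pts(j, 2);
      d[j] = {dx * dx + dy * dy + dz * dz, j};
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int c = 0; c < k; ++c) out(i, c) = d[c].second + 1;  // 1-based
  }
  return out;
}

// ---------------------------------------------------------------------------
// ray-cast point-in-closed-surface
// ---------------------------------------------------------------------------

static int ray_hit(const double* o, const double* dir, const double* A,
                   const double* B, const double* C) {
  // Moller-Trumbore; returns 1 hit, 0 miss, -1 marginal (retry another ray)
  double e1[3], e2[3], pv[3];
  vsub(B, A, e1); vsub(C, A, e2);
  vcross(dir, e2, pv);
  const double det = vdot(e1, pv);
  double lscale = std::sqrt(vdot(e1, e1)) * std::sqrt(vdot(e2, e2));
  if (std::fabs(det) < 1e-12 * std::max(lscale, 1e-300)) return -1;
  const double inv = 1.0 / det;
  double tv[3]; vsub(o, A, tv);
  const double u = vdot(tv, pv) * inv;
  const double tolb = 1e-10;
  if (u < -tolb || u > 1.0 + tolb) return 0;
  double qv[3]; vcross(tv, e1, qv);
  const double v = vdot(qv, dir) * inv;
  if (v < -tolb || u + v > 1.0 + tolb) return 0;
  const double t = vdot(e2, qv) * inv;
  if (t <= 1e-12) return (std::fabs(t) < 1e-12) ? -1 : 0;
  // near an edge / vertex: ask for a retry to stay robust
  if (u < tolb * 10 || v < tolb * 10 || u + v > 1.0 - tolb * 10) return -1;
  return 1;
}

// [[Rcpp::export]]
LogicalVector cb_points_inside(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int N = pts.nrow(), M = F.nrow();
  LogicalVector inside(N);
  // fixed irrational-direction pool: marginal hits trigger the next direction
  const double dirs[8][3] = {
    {0.5380018, 0.6758370, 0.5034296}, {-0.2759802, 0.8353031, 0.4755285},
    {0.7071068, -0.3535534, 0.6123724}, {-0.5773503, -0.5773503, 0.5773503},
    {0.1104315, 0.9701425, -0.2158221}, {0.8017837, 0.2672612, -0.5345225},
    {-0.4082483, 0.4082483, 0.8164966}, {0.9486833, -0.3162278, 0.0},
  };
  for (int i = 0; i < N; ++i) {
    double o[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    bool done = false;
    for (int r = 0; r < 8 && !done; ++r) {
      const double* dir = dirs[r];
      int count = 0;
      bool marginal = false;
      for (int j = 0; j < M; ++j) {
        double A[3], B[3], C[3];
        const int a = F(j, 0), b = F(j, 1), c = F(j, 2);
        for (int k = 0; k < 3; ++k) { A[k] = V(a, k); B[k] = V(b, k); C[k] = V(c, k); }
        const int h = ray_hit(o, dir, A, B, C);
        if (h < 0) { marginal = true; break; }
        count += h;
      }
      if (!marginal) { inside[i] = (count % 2) == 1; done = true; }
    }
    if (!done) stop("ray casting failed for point %d (degenerate geometry)", i + 1);
  }
  return inside;
}

// ---------------------------------------------------------------------------
// treecode (Barnes-Hut with Cartesian Taylor expansions)
// ---------------------------------------------------------------------------

struct TCell {
  double c[3];      // expansion center (bbox center of contained points)
  double radius;    // max distance from center to a contained point
  int start, end;   // range into perm
  int child[8];     // -1 if none
  bool leaf;
  std::vector<double> mom;
};

struct Tree {
  std::vector<TCell> cells;
  std::vector<int> perm;
  int order, nm;
  std::vector<int> mi, mj, mk;               // multi-index per moment slot
  std::vector<int> idx_up[3];                // index of k + e_i (orders 0..P -> 0..P+1)
  int nb;                                    // number of b-coefficients (order P+1)
  std::vector<int> bi, bj, bk;
};

static int midx_count(int P) { return (P + 1) * (P + 2) * (P + 3) / 6; }

static void enumerate_multi(int P, std::vector<int>& ii, std::vector<int>& jj,
                            std::vector<int>& kk, std::vector<int>& table, int dim) {
  table.assign(dim * dim * dim, -1);
  int c = 0;
  for (int n = 0; n <= P; ++n)
    for (int a = n; a >= 0; --a)
      for (int b = n - a; b >= 0; --b) {
        const int d = n - a - b;
        ii.push_back(a); jj.push_back(b); kk.push_back(d);
        table[(a * dim + b) * dim + d] = c;
        ++c;
      }
}

static void build_cell(Tree& tr, NumericMatrix& src, int start, int end,
                       int leaf_size, int depth, int& out_id) {
  TCell cell;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int q = start; q < end; ++q) {
    const int j = tr.perm[q];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], src(j, k));
      hi[k] = std::max(hi[k], src(j, k));
    }
  }
  for (int k = 0; k < 3; ++k) cell.c[k] = 0.5 * (lo[k] + hi[k]);
  double r2max = 0.0;
  for (int q = start; q < end; ++q) {
    const int j = tr.perm[q];
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      const double d = src(j, k) - cell.c[k];
      d2 += d * d;
    }
    r2max = std::max(r2max, d2);
  }
  cell.radius = std::sqrt(r2max);
  cell.start = start; cell.end = end;
  for (int k = 0; k < 8; ++k) cell.child[k] = -1;
  cell.leaf = (end - start <= leaf_size) || depth >= 24 || cell.radius <= 0.0;
  const int id = out_id = (int)tr.cells.size();
  tr.cells.push_back(cell);
  if (!tr.cells[id].leaf) {
    // partition points into octants about the center
    std::vector<int> buckets[8];
    for (int q = start; q < end; ++q) {
      const int j = tr.perm[q];
      int oc = 0;
      if (src(j, 0) > tr.cells[id].c[0]) oc |= 1;
      if (src(j, 1) > tr.cells[id].c[1]) oc |= 2;
      if (src(j, 2) > tr.cells[id].c[2]) oc |= 4;
      buckets[oc].push_back(j);
    }
    int pos = start;
    for (int oc = 0; oc < 8; ++oc) {
      if (buckets[oc].empty()) continue;
      const int s = pos;
      for (int j : buckets[oc]) tr.perm[pos++] = j;
      int cid;
      build_cell(tr, src, s, pos, leaf_size, depth + 1, cid);
      tr.cells[id].child[oc] = cid;
    }
  }
}

static void cell_moments(Tree& tr, NumericMatrix& src, NumericVector& w, int id) {
  TCell& cell = tr.cells[id];
  cell.mom.assign(tr.nm, 0.0);
  const int P = tr.order;
  std::vector<double> px(P + 1), py(P + 1), pz(P + 1);
  for (int q = cell.start; q < cell.end; ++q) {
    const int j = tr.perm[q];
    const double dx = src(j, 0) - cell.c[0];
    const double dy = src(j, 1) - cell.c[1];
    const double dz = src(j, 2) - cell.c[2];
    px[0] = py[0] = pz[0] = 1.0;
    for (int n = 1; n <= P; ++n) {
      px[n] = px[n - 1] * dx; py[n] = py[n - 1] * dy; pz[n] = pz[n - 1] * dz;
    }
    const double wj = w[j];
    for (int m = 0; m < tr.nm; ++m)
      cell.mom[m] += wj * px[tr.mi[m]] * py[tr.mj[m]] * pz[tr.mk[m]];
  }
  if (!cell.leaf)
    for (int oc = 0; oc < 8; ++oc)
      if (cell.child[oc] >= 0) cell_moments(tr, src, w, cell.child[oc]);
}

// Taylor coefficients b_k of 1/|x - y| about y = 0 (coefficients of y^k),
// evaluated for target offset x, all |k| <= P+1.
static void taylor_b(const Tree& tr, const double* x, std::vector<double>& b) {
  const int P1 = tr.order + 1;
  const double r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
  const int dim = P1 + 2;
  // dense table indexed (i, j, k)
  auto at = [&](int i, int j, int k) -> double& {
    return b[(i * dim + j) * dim + k];
  };
  // only entries with i+j+k <= P+1 are ever read, and each is written
  // before any read, so the dense table needs no zero fill
  at(0, 0, 0) = 1.0 / std::sqrt(r2);
  for (int n = 1; n <= P1; ++n) {
    for (int i = n; i >= 0; --i)
      for (int j = n - i; j >= 0; --j) {
        const int k = n - i - j;
        double v = 0.0;
        if (i >= 1) v += x[0] * at(i - 1, j, k);
        if (j >= 1) v += x[1] * at(i, j - 1, k);
        if (k >= 1) v += x[2] * at(i, j, k - 1);
        v *= (2.0 * n - 1.0);
        double u = 0.0;
        if (i >= 2) u += at(i - 2, j, k);
        if (j >= 2) u += at(i, j - 2, k);
        if (k >= 2) u += at(i, j, k - 2);
        at(i, j, k) = (v - (n - 1.0) * u) / (n * r2);
      }
  }
}

// [[Rcpp::export]]
List cb_treecode_eval(NumericMatrix src, NumericVector w, NumericMatrix tgt,
                      IntegerVector excl, double theta, int order,
                      int leaf_size, bool want_pot, bool want_field) {
  const int M = src.nrow(), N = tgt.nrow();
  if (M == 0 || N == 0)
    return List::create(_["potential"] = NumericVector(N),
                        _["field"] = NumericMatrix(N, 3));
  Tree tr;
  tr.order = order;
  tr.nm = midx_count(order);
  tr.nb = midx_count(order + 1);
  std::vector<int> table;
  enumerate_multi(order, tr.mi, tr.mj, tr.mk, table, order + 2);
  tr.perm.resize(M);
  for (int j = 0; j < M; ++j) tr.perm[j] = j;
  int root;
  build_cell(tr, src, 0, M, leaf_size, 0, root);
  cell_moments(tr, src, w, 0);

  NumericVector pot(want_pot ? N : 0);
  NumericMatrix field(want_field ? N : 0, 3);
  const int dim = order + 3;
  std::vector<double> b(dim * dim * dim);
  auto bat = [&](int i, int j, int k) { return b[(i * dim + j) * dim + k]; };
  std::vector<int> stack;
  stack.reserve(256);

  for (int i = 0; i < N; ++i) {
    const double tx = tgt(i, 0), ty = tgt(i, 1), tz = tgt(i, 2);
    const int skip = (excl.size() == N) ? excl[i] : -1;
    double p = 0.0, fx = 0.0, fy = 0.0, fz = 0.0;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      const int id = stack.back();
      stack.pop_back();
      const TCell& cell = tr.cells[id];
      const double dx = tx - cell.c[0], dy = ty - cell.c[1], dz = tz - cell.c[2];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (cell.radius < theta * d) {
        const double xo[3] = {dx, dy, dz};
        taylor_b(tr, xo, b);
        for (int m = 0; m < tr.nm; ++m) {
          const int a = tr.mi[m], bb = tr.mj[m], c = tr.mk[m];
          const double mu = cell.mom[m];
          if (want_pot) p += mu * bat(a, bb, c);
          if (want_field) {
            fx += mu * (a + 1) * bat(a + 1, bb, c);
            fy += mu * (bb + 1) * bat(a, bb + 1, c);
            fz += mu * (c + 1) * bat(a, bb, c + 1);
          }
        }
      } else if (cell.leaf) {
        for (int q = cell.start; q < cell.end; ++q) {
          const int j = tr.perm[q];
          if (j == skip) continue;
          const double ddx = tx - src(j, 0), ddy = ty - src(j, 1), ddz = tz - src(j, 2);
          const double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (r2 <= 0.0) stop("coincident source and target point (pair %d, %d)", i + 1, j + 1);
          const double rinv = 1.0 / std::sqrt(r2);
          const double wr = w[j] * rinv;
          if (want_pot) p += wr;
          if (want_field) {
            const double s = wr * rinv * rinv;
            fx += s * ddx; fy += s * ddy; fz += s * ddz;
          }
        }
      } else {
        for (int oc = 0; oc < 8; ++oc)
          if (cell.child[oc] >= 0) stack.push_back(cell.child[oc]);
      }
    }
    if (want_pot) pot[i] = p / FOURPI;
    if (want_field) {
      field(i, 0) = fx / FOURPI; field(i, 1) = fy / FOURPI; field(i, 2) = fz / FOURPI;
    }
  }
  return List::create(_["potential"] = pot, _["field"] = field);
}
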