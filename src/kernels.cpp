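// Voxel-grid kernels: rank filtering, labeling, distance transforms,
// fast marching, marker watershed, isosurfacing and mesh voxelization.
// All grids are column-major (R array layout), 0-based indices internally.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k) ;
}

// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector x, IntegerVector dim, int kern) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = kern / 2;
  NumericVector out(x.size());
  std::vector<double> buf;
  buf.reserve((size_t)kern * kern * kern);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -r; dk <= r; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1); // replicate border
          for (int dj = -r; dj <= r; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -r; di <= r; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              buf.push_back(x[idx3(ii, jj, kk, nx, ny)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[idx3(i, j, k, nx, ny)] = buf[m];
      }
  return out;
}

// 26-connected component labeling of a logical mask; labels 1..K, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int cur = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            long w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double num = (f[q] + (double)q * q * h * h) - (f[v[k]] + (double)v[k] * v[k] * h * h);
      s = num / (2.0 * h * h * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (world units) from every TRUE voxel to the nearest FALSE
// voxel; FALSE voxels get 0. Anisotropic spacing supported.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  // large finite sentinel: infinities break the parabola intersections
  double diam = nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  const double BIG = 4.0 * diam * diam;
  std::vector<double> g(n);
  for (long s = 0; s < n; ++s) g[s] = mask[s] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = g[idx3(i, j, k, nx, ny)]; if (f[i] == 0.0) any = true; }
      if (!any) continue; // stays BIG, resolved by later passes
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }
  NumericVector out(n);
  for (long s = 0; s < n; ++s) out[s] = std::sqrt(std::min(g[s], BIG));
  out.attr("dim") = dim;
  return out;
}

// Fast Marching solution of |grad T| = 1/speed(x) on the voxels where
// speed > 0 and finite. sources are 0-based linear indices with T = 0.
// [[Rcpp::export]]
NumericVector cpp_fmm(NumericVector speed, IntegerVector dim, NumericVector spacing,
                      IntegerVector sources, NumericVector source_values) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> T(n, INF);
  std::vector<char> state(n, 0); // 0 far, 1 trial, 2 accepted
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  for (int s = 0; s < sources.size(); ++s) {
    long v = sources[s];
    if (v < 0 || v >= n) stop("source index out of range");
    double t0 = (source_values.size() == sources.size()) ? source_values[s] : 0.0;
    if (t0 < T[v]) {
      T[v] = t0; state[v] = 1;
      heap.push(Node(t0, v));
    }
  }

  const int di[3] = {1, nx, 0};
  (void)di;
  while (!heap.empty()) {
    Node top = heap.top(); heap.pop();
    long v = top.second;
    if (state[v] == 2) continue;
    state[v] = 2;
    int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
    // relax 6-neighbors
    for (int ax = 0; ax < 3; ++ax)
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        int ii = i + (ax == 0 ? sgn : 0);
        int jj = j + (ax == 1 ? sgn : 0);
        int kk = k + (ax == 2 ? sgn : 0);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long w = idx3(ii, jj, kk, nx, ny);
        if (state[w] == 2) continue;
        double F = speed[w];
        if (!(F > 0.0) || !std::isfinite(F)) continue;
        // second-order upwind quadratic update at w (falls back to first
        // order per axis when only one accepted upwind value exists)
        double al[3], be[3], tm[3];
        int m = 0;
        int wi = ii, wj = jj, wk = kk;
        for (int bx = 0; bx < 3; ++bx) {
          double best = INF, second = INF;
          for (int s2 = -1; s2 <= 1; s2 += 2) {
            int pi = wi + (bx == 0 ? s2 : 0);
            int pj = wj + (bx == 1 ? s2 : 0);
            int pk = wk + (bx == 2 ? s2 : 0);
            if (pi < 0 || pj < 0 || pk < 0 || pi >= nx || pj >= ny || pk >= nz) continue;
            long p = idx3(pi, pj, pk, nx, ny);
            if (state[p] != 2 || !(T[p] < best)) continue;
            best = T[p];
            second = INF;
            int qi = pi + (bx == 0 ? s2 : 0);
            int qj = pj + (bx == 1 ? s2 : 0);
            int qk = pk + (bx == 2 ? s2 : 0);
            if (qi >= 0 && qj >= 0 && qk >= 0 && qi < nx && qj < ny && qk < nz) {
              long q = idx3(qi, qj, qk, nx, ny);
              if (state[q] == 2 && T[q] <= T[p]) second = T[q];
            }
          }
          if (!std::isfinite(best)) continue;
          double hh = spacing[bx];
          if (std::isfinite(second)) {
            al[m] = 1.5 / hh;
            be[m] = (2.0 * best - 0.5 * second) / hh;
          } else {
            al[m] = 1.0 / hh;
            be[m] = best / hh;
          }
          tm[m] = best;
          ++m;
        }
        if (m == 0) continue;
        // sort by upwind value ascending
        for (int p1 = 0; p1 < m; ++p1)
          for (int p2 = p1 + 1; p2 < m; ++p2)
            if (tm[p2] < tm[p1]) {
              std::swap(tm[p1], tm[p2]); std::swap(al[p1], al[p2]);
              std::swap(be[p1], be[p2]);
            }
        double slo = 1.0 / F; // slowness
        double t = INF;
        for (int use = m; use >= 1; --use) {
          // solve sum_{d<use} (al_d t - be_d)^2 = slo^2, require t >= tm[use-1]
          double A = 0, B = 0, C = -slo * slo;
          for (int d0 = 0; d0 < use; ++d0) {
            A += al[d0] * al[d0];
            B += al[d0] * be[d0];
            C += be[d0] * be[d0];
          }
          double disc = B * B - A * C;
          if (disc < 0) continue;
          double cand = (B + std::sqrt(disc)) / A;
          if (use == 1 || cand >= tm[use - 1]) { t = cand; break; }
        }
        if (t < T[w]) {
          T[w] = t;
          state[w] = 1;
          heap.push(Node(t, w));
        }
      }
  }
  NumericVector out(n);
  for (long s = 0; s < n; ++s) out[s] = T[s];
  out.attr("dim") = dim;
  return out;
}

// Marker-based watershed (priority flood, 6-connectivity) of `height` over
// the domain `domain`; markers > 0 seed labels, flooding never crosses
// voxels outside the domain.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector markers,
                            LogicalVector domain, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;
  for (long s = 0; s < n; ++s)
    if (markers[s] > 0 && domain[s]) { lab[s] = markers[s]; heap.push(Node(height[s], s)); }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!heap.empty()) {
    Node top = heap.top(); heap.pop();
    long v = top.second;
    int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long w = idx3(ii, jj, kk, nx, ny);
      if (!domain[w] || lab[w]) continue;
      lab[w] = lab[v];
      heap.push(Node(height[w], w));
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// TRUE where x is >= all of its 26 neighbors (restricted to finite values).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima26(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  LogicalVector out(n, false);
  for (long s = 0; s < n; ++s) {
    if (!std::isfinite(x[s])) continue;
    int i = s % nx, j = (s / nx) % ny, k = s / ((long)nx * ny);
    bool mx = true;
    for (int dk = -1; dk <= 1 && mx; ++dk)
      for (int dj = -1; dj <= 1 && mx; ++dj)
        for (int di = -1; di <= 1 && mx; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          double xv = x[idx3(ii, jj, kk, nx, ny)];
          if (std::isfinite(xv) && xv > x[s]) mx = false;
        }
    out[s] = mx;
  }
  out.attr("dim") = dim;
  return out;
}

// ---- Marching tetrahedra -------------------------------------------------
// Uniform Kuhn decomposition of each cell into 6 tetrahedra around the
// main diagonal; shared vertices welded on lattice-edge keys so closed
// level sets come out watertight and 2-manifold.

struct MTState {
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static int mt_edge_vertex(MTState& st, long iA, long iB, double fA, double fB,
                          const double* pA, const double* pB, double level) {
  if (iA > iB) { std::swap(iA, iB); std::swap(fA, fB); const double* t = pA; pA = pB; pB = t; }
  uint64_t key = (uint64_t)iA * 0x100000000ULL ^ (uint64_t)iB;
  // combine uniquely: lattice ids < 2^31 so pack as (iA<<32)|iB
  key = ((uint64_t)iA << 32) | (uint64_t)iB;
  std::unordered_map<uint64_t, int>::iterator it = st.vmap.find(key);
  if (it != st.vmap.end()) return it->second;
  double t = (level - fA) / (fB - fA);
  if (t < 1e-8) t = 1e-8;
  if (t > 1.0 - 1e-8) t = 1.0 - 1e-8;
  int id = (int)st.vx.size();
  st.vx.push_back(pA[0] + t * (pB[0] - pA[0]));
  st.vy.push_back(pA[1] + t * (pB[1] - pA[1]));
  st.vz.push_back(pA[2] + t * (pB[2] - pA[2]));
  st.vmap[key] = id;
  return id;
}

static void mt_emit(MTState& st, int a, int b, int c,
                    const double* cpos, const double* cneg) {
  // orient so the normal points from the positive (interior) side outward
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double dx = cneg[0] - cpos[0], dy = cneg[1] - cpos[1], dz = cneg[2] - cpos[2];
  if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(b, c);
  st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, NumericVector spacing,
                    NumericVector origin, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  MTState st;
  double P[8][3]; double F[8]; long L[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          L[c] = idx3(ci, cj, ck, nx, ny);
          F[c] = field[L[c]];
          P[c][0] = origin[0] + ci * spacing[0];
          P[c][1] = origin[1] + cj * spacing[1];
          P[c][2] = origin[2] + ck * spacing[2];
          if (F[c] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int pos[4], neg[4]; int np = 0, nn = 0;
          for (int c = 0; c < 4; ++c) {
            if (F[vi[c]] > level) pos[np++] = vi[c]; else neg[nn++] = vi[c];
          }
          if (np == 0 || np == 4) continue;
          double cpos[3] = {0, 0, 0}, cneg[3] = {0, 0, 0};
          for (int c = 0; c < np; ++c) { cpos[0] += P[pos[c]][0] / np; cpos[1] += P[pos[c]][1] / np; cpos[2] += P[pos[c]][2] / np; }
          for (int c = 0; c < nn; ++c) { cneg[0] += P[neg[c]][0] / nn; cneg[1] += P[neg[c]][1] / nn; cneg[2] += P[neg[c]][2] / nn; }
          if (np == 1) {
            int a = mt_edge_vertex(st, L[pos[0]], L[neg[0]], F[pos[0]], F[neg[0]], P[pos[0]], P[neg[0]], level);
            int b = mt_edge_vertex(st, L[pos[0]], L[neg[1]], F[pos[0]], F[neg[1]], P[pos[0]], P[neg[1]], level);
            int c = mt_edge_vertex(st, L[pos[0]], L[neg[2]], F[pos[0]], F[neg[2]], P[pos[0]], P[neg[2]], level);
            mt_emit(st, a, b, c, cpos, cneg);
          } else if (np == 3) {
            int a = mt_edge_vertex(st, L[neg[0]], L[pos[0]], F[neg[0]], F[pos[0]], P[neg[0]], P[pos[0]], level);
            int b = mt_edge_vertex(st, L[neg[0]], L[pos[1]], F[neg[0]], F[pos[1]], P[neg[0]], P[pos[1]], level);
            int c = mt_edge_vertex(st, L[neg[0]], L[pos[2]], F[neg[0]], F[pos[2]], P[neg[0]], P[pos[2]], level);
            mt_emit(st, a, b, c, cpos, cneg);
          } else { // 2-2
            int a = mt_edge_vertex(st, L[pos[0]], L[neg[0]], F[pos[0]], F[neg[0]], P[pos[0]], P[neg[0]], level);
            int b = mt_edge_vertex(st, L[pos[0]], L[neg[1]], F[pos[0]], F[neg[1]], P[pos[0]], P[neg[1]], level);
            int c = mt_edge_vertex(st, L[pos[1]], L[neg[1]], F[pos[1]], F[neg[1]], P[pos[1]], P[neg[1]], level);
            int d = mt_edge_vertex(st, L[pos[1]], L[neg[0]], F[pos[1]], F[neg[0]], P[pos[1]], P[neg[0]], level);
            mt_emit(st, a, b, c, cpos, cneg);
            mt_emit(st, a, c, d, cpos, cneg);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v]; }
  for (int f = 0; f < nf; ++f) { Fm(f, 0) = st.fa[f] + 1; Fm(f, 1) = st.fb[f] + 1; Fm(f, 2) = st.fc[f] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Parity-fill voxelization of a closed triangle mesh: a voxel is inside if
// the +z ray from its (jittered) center crosses the surface an odd number
// of times below it.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces, IntegerVector dim,
                           NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long ncol = (long)nx * ny;
  std::vector<std::vector<double> > crossings(ncol);
  const double jx = 0.1234e-3 * spacing[0], jy = 0.5678e-3 * spacing[1];
  for (int f = 0; f < faces.nrow(); ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue; // vertical triangle: measure-zero for jittered rays
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - origin[0] - jx) / spacing[0]);
    int i1 = (int)std::floor((xmax - origin[0] - jx) / spacing[0]);
    int j0 = (int)std::ceil((ymin - origin[1] - jy) / spacing[1]);
    int j1 = (int)std::floor((ymax - origin[1] - jy) / spacing[1]);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + jy;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + i * spacing[0] + jx;
        double l1 = ((px - ax) * (cy - ay) - (py - ay) * (cx - ax)) / det;
        double l2 = ((bx - ax) * (py - ay) - (by - ay) * (px - ax)) / det;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double z = az + l1 * (bz - az) + l2 * (cz - az);
        crossings[i + (long)nx * j].push_back(z);
      }
    }
  }
  LogicalVector out((long)ncol * nz, false);
  for (long cidx = 0; cidx < ncol; ++cidx) {
    std::vector<double>& zs = crossings[cidx];
    if (zs.empty()) continue;
    std::sort(zs.begin(), zs.end());
    size_t npair = zs.size() / 2;
    for (size_t p = 0; p < npair; ++p) {
      double zlo = zs[2 * p], zhi = zs[2 * p + 1];
      int k0 = (int)std::ceil((zlo - origin[2]) / spacing[2]);
      int k1 = (int)std::floor((zhi - origin[2]) / spacing[2]);
      k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
      for (int k = k0; k <= k1; ++k) out[cidx + ncol * (long)k] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}
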