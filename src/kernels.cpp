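// Voxel-grid kernels: anisotropic Euclidean distance transform, connected
// components, topology-preserving curve thinning, and least-cost path search.
// All grids are column-major (R array layout), linear index = i + nx*(j + ny*k).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample pitch sp.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double sp) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double qp = q * sp;
    double s = 0.0;
    while (true) {
      double vp = v[k] * sp;
      s = ((f[q] + qp * qp) - (f[v[k]] + vp * vp)) / (2.0 * qp - 2.0 * vp);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qp = q * sp;
    while (z[k + 1] < qp) ++k;
    double vp = v[k] * sp;
    d[q] = (qp - vp) * (qp - vp) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest feature
// voxel center. feature: logical array; spacing: mm per axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = feature[t] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + nxy * k];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, 3D; connectivity 6 or 26. Labels 1..ncomp in
// scan order of the first voxel encountered, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / ((R_xlen_t)nx * ny));
      int rem = (int)(p % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// 2D 4-connected labelling of one slice (nx fastest).
// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector mask, int nx, int ny) {
  const R_xlen_t n = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  for (int s = 0; s < (int)n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int j = p / nx, i = p % nx;
      for (int t = 0; t < 4; ++t) {
        int ii = i + dx[t], jj = j + dy[t];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int q = ii + nx * jj;
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topology machinery for thinning (Bertrand/Malandain simple-point test).

struct NbGeom {
  // 26 offsets and their pairwise 26-adjacency; 18-neighborhood offsets and
  // their pairwise 6-adjacency, with a flag for face neighbors of the center.
  std::array<std::array<int, 3>, 26> off26;
  bool adj26[26][26];
  std::array<std::array<int, 3>, 18> off18;
  bool adj6_18[18][18];
  bool face18[18];
  NbGeom() {
    int a = 0, b = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          off26[a++] = {dx, dy, dz};
          int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (m <= 2) {
            off18[b] = {dx, dy, dz};
            face18[b] = (m == 1);
            ++b;
          }
        }
    for (int p = 0; p < 26; ++p)
      for (int q = 0; q < 26; ++q) {
        int ddx = std::abs(off26[p][0] - off26[q][0]);
        int ddy = std::abs(off26[p][1] - off26[q][1]);
        int ddz = std::abs(off26[p][2] - off26[q][2]);
        adj26[p][q] = (p != q) && ddx <= 1 && ddy <= 1 && ddz <= 1;
      }
    for (int p = 0; p < 18; ++p)
      for (int q = 0; q < 18; ++q) {
        int m = std::abs(off18[p][0] - off18[q][0]) +
                std::abs(off18[p][1] - off18[q][1]) +
                std::abs(off18[p][2] - off18[q][2]);
        adj6_18[p][q] = (p != q) && m == 1;
      }
  }
};

static const NbGeom NB;

static inline bool getvox(const std::vector<uint8_t>& m, int nx, int ny, int nz,
                          int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  return m[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] != 0;
}

// number of 26-connected components of foreground within N26
static int fg26_components(const bool nb[26]) {
  int comp = 0;
  bool seen[26] = {false};
  int stack[26];
  for (int s = 0; s < 26; ++s) {
    if (!nb[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int p = stack[--top];
      for (int q = 0; q < 26; ++q)
        if (nb[q] && !seen[q] && NB.adj26[p][q]) {
          seen[q] = true;
          stack[top++] = q;
        }
    }
  }
  return comp;
}

// number of 6-connected components of background within N18 that touch a face
// neighbor of the center
static int bg6_components(const bool bg[18]) {
  int comp = 0;
  bool seen[18] = {false};
  int stack[18];
  for (int s = 0; s < 18; ++s) {
    if (!bg[s] || seen[s] || !NB.face18[s]) continue;  // seed only from faces
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int p = stack[--top];
      for (int q = 0; q < 18; ++q)
        if (bg[q] && !seen[q] && NB.adj6_18[p][q]) {
          seen[q] = true;
          stack[top++] = q;
        }
    }
  }
  return comp;
}

static inline void fill_neighborhood(const std::vector<uint8_t>& m, int nx,
                                     int ny, int nz, int i, int j, int k,
                                     bool nb26[26], bool bg18[18], int& nfg) {
  nfg = 0;
  for (int t = 0; t < 26; ++t) {
    bool v = getvox(m, nx, ny, nz, i + NB.off26[t][0], j + NB.off26[t][1],
                    k + NB.off26[t][2]);
    nb26[t] = v;
    if (v) ++nfg;
  }
  for (int t = 0; t < 18; ++t)
    bg18[t] = !getvox(m, nx, ny, nz, i + NB.off18[t][0], j + NB.off18[t][1],
                      k + NB.off18[t][2]);
}

static inline bool is_simple(const bool nb26[26], const bool bg18[18]) {
  return fg26_components(nb26) == 1 && bg6_components(bg18) == 1;
}

// Topology-preserving thinning to a unit-width curve skeleton using six
// directional subiterations (delete only voxels whose {-x,+x,-y,+y,-z,+z}
// face neighbor is background, one direction per subpass), with the exact
// simple-point test above and endpoint preservation (<=1 foreground
// 26-neighbor). Within a subpass voxels are processed in order of increasing
// distance-transform value (then scan order) and re-checked at deletion time,
// so the result is deterministic, homotopic, and symmetric enough to retract
// blunt tube ends onto the medial axis instead of drifting to a cap rim.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim,
                              NumericVector dt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> m(n);
  std::vector<R_xlen_t> fg;
  for (R_xlen_t t = 0; t < n; ++t) {
    m[t] = mask[t] ? 1 : 0;
    if (m[t]) fg.push_back(t);
  }
  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool nb26[26];
  bool bg18[18];
  int nfg;

  typedef std::pair<double, R_xlen_t> QE;  // (dt, index)
  std::vector<QE> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t t = 0; t < fg.size(); ++t) {
        R_xlen_t p = fg[t];
        if (!m[p]) continue;
        int k = (int)(p / ((R_xlen_t)nx * ny));
        int rem = (int)(p % ((R_xlen_t)nx * ny));
        int j = rem / nx, i = rem % nx;
        if (getvox(m, nx, ny, nz, i + dirs[d][0], j + dirs[d][1],
                   k + dirs[d][2]))
          continue;  // not a border voxel in this direction
        cand.push_back(QE(dt[p], p));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t t = 0; t < cand.size(); ++t) {
        R_xlen_t p = cand[t].second;
        if (!m[p]) continue;
        int k = (int)(p / ((R_xlen_t)nx * ny));
        int rem = (int)(p % ((R_xlen_t)nx * ny));
        int j = rem / nx, i = rem % nx;
        if (getvox(m, nx, ny, nz, i + dirs[d][0], j + dirs[d][1],
                   k + dirs[d][2]))
          continue;
        fill_neighborhood(m, nx, ny, nz, i, j, k, nb26, bg18, nfg);
        // Curve-end protection. <=1 neighbor: a tip. Exactly 2 mutually
        // adjacent neighbors: the tip of a 26-connected staircase rod, which
        // plain simple-point thinning would unravel voxel by voxel -- keep
        // it, UNLESS one of the two neighbors itself has only 2 foreground
        // neighbors (a terminal 3-voxel triangle, which must collapse so a
        // clean leaf can form).
        if (nfg <= 1) continue;
        if (nfg == 2) {
          int mindeg = 27;
          for (int t = 0; t < 26; ++t) {
            if (!nb26[t]) continue;
            int ii = i + NB.off26[t][0], jj = j + NB.off26[t][1],
                kk = k + NB.off26[t][2];
            int deg = 0;
            for (int u = 0; u < 26; ++u)
              if (getvox(m, nx, ny, nz, ii + NB.off26[u][0],
                         jj + NB.off26[u][1], kk + NB.off26[u][2]))
                ++deg;
            if (deg < mindeg) mindeg = deg;
          }
          if (mindeg >= 3) continue;  // staircase tip: keep
        }
        if (!is_simple(nb26, bg18)) continue;  // would change topology
        m[p] = 0;
        changed = true;
      }
    }
    // compact the foreground list between rounds
    size_t w = 0;
    for (size_t t = 0; t < fg.size(); ++t)
      if (m[fg[t]]) fg[w++] = fg[t];
    fg.resize(w);
  }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = m[t] != 0;
  return out;
}

// Count foreground 26-neighbors of every voxel (used for skeleton leaves).
// [[Rcpp::export]]
IntegerVector cpp_count_nb26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> m(n);
  for (R_xlen_t t = 0; t < n; ++t) m[t] = mask[t] ? 1 : 0;
  IntegerVector out(n, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t p = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!m[p]) continue;
        int c = 0;
        for (int t = 0; t < 26; ++t)
          if (getvox(m, nx, ny, nz, i + NB.off26[t][0], j + NB.off26[t][1],
                     k + NB.off26[t][2]))
            ++c;
        out[p] = c;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Least-cost path between two foreground voxels on the 26-connected voxel
// graph. Edge cost = physical step length (mm) * nodew[target]. Returns
// 0-based linear indices from src to dst, or empty vector if unreachable.
// [[Rcpp::export]]
IntegerVector cpp_dijkstra(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing, NumericVector nodew,
                           double src, double dst) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t s = (R_xlen_t)src, d = (R_xlen_t)dst;

  std::vector<std::array<int, 3>> offs;
  std::vector<double> steps;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs.push_back({dx, dy, dz});
        double ex = dx * spacing[0], ey = dy * spacing[1], ez = dz * spacing[2];
        steps.push_back(std::sqrt(ex * ex + ey * ey + ez * ez));
      }

  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<R_xlen_t> prev(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[s] = 0.0;
  pq.push(QE(0.0, s));
  while (!pq.empty()) {
    double dd = pq.top().first;
    R_xlen_t p = pq.top().second;
    pq.pop();
    if (dd > dist[p]) continue;
    if (p == d) break;
    int k = (int)(p / ((R_xlen_t)nx * ny));
    int rem = (int)(p % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (size_t t = 0; t < offs.size(); ++t) {
      int ii = i + offs[t][0], jj = j + offs[t][1], kk = k + offs[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (!mask[q]) continue;
      double nd = dd + steps[t] * nodew[q];
      if (nd < dist[q]) {
        dist[q] = nd;
        prev[q] = p;
        pq.push(QE(nd, q));
      }
    }
  }
  if (!std::isfinite(dist[d])) return IntegerVector(0);
  std::vector<R_xlen_t> rev;
  for (R_xlen_t p = d; p != -1; p = prev[p]) rev.push_back(p);
  IntegerVector path(rev.size());
  for (size_t t = 0; t < rev.size(); ++t)
    path[t] = (int)rev[rev.size() - 1 - t];
  return path;
}
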