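#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Spatial neighbor primitives shared by the filtering, segmentation,
// curvature and descriptor stages. Clouds here are a few times 10^4 points,
// so kNN uses brute-force partial selection while the tol-graph clustering
// uses a voxel hash to stay near-linear.

static inline double sqdist(const NumericMatrix& X, int i, int j) {
  double dx = X(i, 0) - X(j, 0);
  double dy = X(i, 1) - X(j, 1);
  double dz = X(i, 2) - X(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// k nearest neighbors of every point (self excluded), 1-based indices.
// Uses a uniform voxel grid with an expanding ring search: the search stops
// once the k-th best distance is closer than the nearest possible cell of
// the next ring.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix X, int k) {
  int n = X.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo[d] = std::min(lo[d], X(i, d));
      hi[d] = std::max(hi[d], X(i, d));
    }
  }
  // cell size from the non-degenerate extents (flat or linear clouds keep a
  // sane grid); then coarsen until the grid has at most ~8 cells per point
  double ext[3], maxext = 0.0;
  for (int d = 0; d < 3; ++d) {
    ext[d] = hi[d] - lo[d];
    maxext = std::max(maxext, ext[d]);
  }
  if (maxext <= 0) maxext = 1.0;
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(ext[d], 1e-3 * maxext);
  double h = std::cbrt(vol * 4.0 / n);
  if (!(h > 0) || !R_FINITE(h)) h = maxext;
  int nx, ny, nz;
  for (;;) {
    nx = (int)(ext[0] / h) + 1;
    ny = (int)(ext[1] / h) + 1;
    nz = (int)(ext[2] / h) + 1;
    if ((double)nx * ny * nz <= 8.0 * n + 64.0) break;
    h *= 2.0;
  }
  std::vector<std::vector<int> > grid((size_t)nx * ny * nz);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = std::min(nx - 1, (int)((X(i, 0) - lo[0]) / h));
    cj[i] = std::min(ny - 1, (int)((X(i, 1) - lo[1]) / h));
    ck[i] = std::min(nz - 1, (int)((X(i, 2) - lo[2]) / h));
    grid[((size_t)ci[i] * ny + cj[i]) * nz + ck[i]].push_back(i);
  }

  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  typedef std::pair<double, int> DI;
  int max_ring = std::max(std::max(nx, ny), nz);
  for (int i = 0; i < n; ++i) {
    std::priority_queue<DI> heap;  // max-heap of the k best squared dists
    for (int r = 0; r <= max_ring; ++r) {
      if ((int)heap.size() == k) {
        double ring_min = (r - 1) > 0 ? (double)(r - 1) * h : 0.0;
        if (heap.top().first <= ring_min * ring_min) break;
      }
      int a0 = std::max(0, ci[i] - r), a1 = std::min(nx - 1, ci[i] + r);
      int b0 = std::max(0, cj[i] - r), b1 = std::min(ny - 1, cj[i] + r);
      int c0 = std::max(0, ck[i] - r), c1 = std::min(nz - 1, ck[i] + r);
      for (int a = a0; a <= a1; ++a)
        for (int b = b0; b <= b1; ++b)
          for (int c = c0; c <= c1; ++c) {
            // only the shell of the ring (inner cells already visited)
            if (r > 0 && std::abs(a - ci[i]) != r &&
                std::abs(b - cj[i]) != r && std::abs(c - ck[i]) != r)
              continue;
            const std::vector<int>& cell = grid[((size_t)a * ny + b) * nz + c];
            for (size_t t = 0; t < cell.size(); ++t) {
              int j = cell[t];
              if (j == i) continue;
              double d2 = sqdist(X, i, j);
              if ((int)heap.size() < k) heap.push(DI(d2, j));
              else if (d2 < heap.top().first) {
                heap.pop();
                heap.push(DI(d2, j));
              }
            }
          }
    }
    for (int q = k - 1; q >= 0; --q) {
      idx(i, q) = heap.top().second + 1;
      dst(i, q) = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

struct CellKey {
  long long a, b, c;
  bool operator==(const CellKey& o) const { return a == o.a && b == o.b && c == o.c; }
};
struct CellHash {
  size_t operator()(const CellKey& k) const {
    size_t h = std::hash<long long>()(k.a);
    h ^= std::hash<long long>()(k.b) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    h ^= std::hash<long long>()(k.c) + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
    return h;
  }
};

static inline CellKey cell_of(const NumericMatrix& X, int i, double h) {
  CellKey k;
  k.a = (long long)std::floor(X(i, 0) / h);
  k.b = (long long)std::floor(X(i, 1) / h);
  k.c = (long long)std::floor(X(i, 2) / h);
  return k;
}

// Connected components of the graph linking points closer than tol.
// Returns 1-based component labels in first-touch order.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(NumericMatrix X, double tol) {
  int n = X.nrow();
  std::unordered_map<CellKey, std::vector<int>, CellHash> grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) grid[cell_of(X, i, tol)].push_back(i);
  IntegerVector lab(n, 0);
  double tol2 = tol * tol;
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int i = q.front();
      q.pop();
      CellKey ck = cell_of(X, i, tol);
      for (long long da = -1; da <= 1; ++da)
        for (long long db = -1; db <= 1; ++db)
          for (long long dc = -1; dc <= 1; ++dc) {
            CellKey nk;
            nk.a = ck.a + da; nk.b = ck.b + db; nk.c = ck.c + dc;
            std::unordered_map<CellKey, std::vector<int>, CellHash>::iterator it = grid.find(nk);
            if (it == grid.end()) continue;
            const std::vector<int>& cell = it->second;
            for (size_t t = 0; t < cell.size(); ++t) {
              int j = cell[t];
              if (lab[j] != 0) continue;
              if (sqdist(X, i, j) <= tol2) {
                lab[j] = next;
                q.push(j);
              }
            }
          }
    }
  }
  return lab;
}

static void spfh(const NumericMatrix& X, const NumericMatrix& N, int i,
                 const std::vector<int>& nb, double* bins) {
  for (int b = 0; b < 33; ++b) bins[b] = 0.0;
  double p[3] = {X(i, 0), X(i, 1), X(i, 2)};
  double u[3] = {N(i, 0), N(i, 1), N(i, 2)};
  for (size_t t = 0; t < nb.size(); ++t) {
    int j = nb[t];
    double dv[3] = {X(j, 0) - p[0], X(j, 1) - p[1], X(j, 2) - p[2]};
    double dist = std::sqrt(dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2]);
    if (dist < 1e-12) continue;
    double dn[3] = {dv[0] / dist, dv[1] / dist, dv[2] / dist};
    // v = dn x u, w = u x v (Darboux frame)
    double v[3] = {dn[1] * u[2] - dn[2] * u[1],
                   dn[2] * u[0] - dn[0] * u[2],
                   dn[0] * u[1] - dn[1] * u[0]};
    double vn = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (vn < 1e-9) {
      double ref[3] = {std::fabs(u[0]) < 0.9 ? 1.0 : 0.0,
                       std::fabs(u[0]) < 0.9 ? 0.0 : 1.0, 0.0};
      v[0] = u[1] * ref[2] - u[2] * ref[1];
      v[1] = u[2] * ref[0] - u[0] * ref[2];
      v[2] = u[0] * ref[1] - u[1] * ref[0];
      vn = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    }
    v[0] /= vn; v[1] /= vn; v[2] /= vn;
    double w[3] = {u[1] * v[2] - u[2] * v[1],
                   u[2] * v[0] - u[0] * v[2],
                   u[0] * v[1] - u[1] * v[0]};
    double nq[3] = {N(j, 0), N(j, 1), N(j, 2)};
    double alpha = v[0] * nq[0] + v[1] * nq[1] + v[2] * nq[2];
    double phi = u[0] * dn[0] + u[1] * dn[1] + u[2] * dn[2];
    double theta = std::atan2(w[0] * nq[0] + w[1] * nq[1] + w[2] * nq[2],
                              u[0] * nq[0] + u[1] * nq[1] + u[2] * nq[2]);
    int b1 = (int)((alpha + 1.0) / 2.0 * 11.0);
    int b2 = (int)((phi + 1.0) / 2.0 * 11.0);
    int b3 = (int)((theta + M_PI) / (2.0 * M_PI) * 11.0);
    if (b1 > 10) b1 = 10; if (b1 < 0) b1 = 0;
    if (b2 > 10) b2 = 10; if (b2 < 0) b2 = 0;
    if (b3 > 10) b3 = 10; if (b3 < 0) b3 = 0;
    bins[b1] += 1.0; bins[11 + b2] += 1.0; bins[22 + b3] += 1.0;
  }
}

static void radius_nb(const NumericMatrix& X, int i, double r2,
                      std::vector<int>& out) {
  out.clear();
  int n = X.nrow();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (sqdist(X, i, j) <= r2) out.push_back(j);
  }
}

// FPFH descriptors (33 bins, each 11-bin block normalized to sum 100) for
// the query points (1-based). Rows of X and normals correspond.
// [[Rcpp::export]]
NumericMatrix cpp_fpfh(NumericMatrix X, NumericMatrix normals,
                       IntegerVector queries, double radius) {
  int m = queries.size();
  NumericMatrix out(m, 33);
  double r2 = radius * radius;
  std::vector<int> nb, nb2;
  double bins[33], acc[33];
  for (int q = 0; q < m; ++q) {
    int i = queries[q] - 1;
    radius_nb(X, i, r2, nb);
    if ((int)nb.size() < 5) {
      for (int b = 0; b < 33; ++b) out(q, b) = NA_REAL;
      continue;
    }
    spfh(X, normals, i, nb, acc);
    double buf[33];
    for (size_t t = 0; t < nb.size(); ++t) {
      int j = nb[t];
      radius_nb(X, j, r2, nb2);
      spfh(X, normals, j, nb2, buf);
      double d = std::sqrt(sqdist(X, i, j));
      double wgt = 1.0 / std::max(d, 1e-9) / nb.size();
      for (int b = 0; b < 33; ++b) acc[b] += wgt * buf[b];
    }
    for (int blk = 0; blk < 3; ++blk) {
      double s = 0.0;
      for (int b = 0; b < 11; ++b) s += acc[blk * 11 + b];
      for (int b = 0; b < 11; ++b)
        out(q, blk * 11 + b) = s > 0 ? acc[blk * 11 + b] / s * 100.0 : 0.0;
    }
    (void)bins;
  }
  return out;
}

// Neighbors of selected query points within radius r (self excluded),
// ordered by stored point index. centers are 1-based.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix X, IntegerVector centers, double r) {
  int n = X.nrow(), m = centers.size();
  double r2 = r * r;
  List out(m);
  for (int c = 0; c < m; ++c) {
    int i = centers[c] - 1;
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (sqdist(X, i, j) <= r2) nb.push_back(j + 1);
    }
    out[c] = wrap(nb);
  }
  return out;
}
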