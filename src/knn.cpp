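#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Hash key for a 3D integer cell.
static inline long long cell_key(long long ix, long long iy, long long iz) {
  // 21 bits per axis, offset to keep indices positive
  const long long off = 1LL << 20;
  return ((ix + off) << 42) | ((iy + off) << 21) | (iz + off);
}

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int>> cells;
};

static Grid build_grid(const NumericMatrix& pts, double cell) {
  Grid g;
  g.cell = cell;
  int n = pts.nrow();
  g.ox = g.oy = g.oz = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    g.ox = std::min(g.ox, pts(i, 0));
    g.oy = std::min(g.oy, pts(i, 1));
    g.oz = std::min(g.oz, pts(i, 2));
  }
  g.cells.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor((pts(i, 0) - g.ox) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - g.oy) / cell);
    long long iz = (long long)std::floor((pts(i, 2) - g.oz) / cell);
    g.cells[cell_key(ix, iy, iz)].push_back(i);
  }
  return g;
}

// k nearest neighbours of every point (excluding itself) via ring expansion
// over a uniform hash grid. Returns 1-based index matrix and distance matrix.
// [[Rcpp::export(name = ".knn_cpp")]]
List knn_cpp(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k >= n) k = n - 1;
  if (k < 1) stop("need at least 2 points for neighbour search");

  // target ~2 points per cell
  double xr = 0, yr = 0, zr = 0;
  {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
           zmin = R_PosInf, zmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
      ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
      zmin = std::min(zmin, pts(i, 2)); zmax = std::max(zmax, pts(i, 2));
    }
    xr = xmax - xmin; yr = ymax - ymin; zr = zmax - zmin;
  }
  // floor each extent at 1% of the largest so degenerate (planar or
  // collinear) clouds still get cells commensurate with point spacing
  double maxr = std::max(xr, std::max(yr, zr));
  if (!(maxr > 0)) maxr = 1.0;
  double vol = std::max(xr, 0.01 * maxr) * std::max(yr, 0.01 * maxr) *
               std::max(zr, 0.01 * maxr);
  double cell = std::cbrt(vol * 2.0 / n);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  long long max_ring = (long long)(maxr / cell) + 2;

  Grid g = build_grid(pts, cell);

  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double, int>> cand;
  cand.reserve(64);

  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    long long cx = (long long)std::floor((px - g.ox) / cell);
    long long cy = (long long)std::floor((py - g.oy) / cell);
    long long cz = (long long)std::floor((pz - g.oz) / cell);
    cand.clear();
    int ring = 0;
    double kth = R_PosInf;
    while (true) {
      // visit shell at Chebyshev radius `ring`
      for (long long dx = -ring; dx <= ring; ++dx) {
        for (long long dy = -ring; dy <= ring; ++dy) {
          for (long long dz = -ring; dz <= ring; ++dz) {
            if (std::max(std::llabs(dx), std::max(std::llabs(dy), std::llabs(dz))) != ring)
              continue;
            auto it = g.cells.find(cell_key(cx + dx, cy + dy, cz + dz));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              double ddx = pts(j, 0) - px, ddy = pts(j, 1) - py, ddz = pts(j, 2) - pz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              cand.push_back(std::make_pair(d2, j));
            }
          }
        }
      }
      if ((int)cand.size() >= k) {
        std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
        kth = std::sqrt(cand[k - 1].first);
        // all points outside the searched shells are at least ring*cell away
        if (kth <= ring * cell) break;
      }
      ++ring;
      // beyond max_ring every point has been visited
      if (ring > max_ring) {
        if ((int)cand.size() < k) stop("neighbour search failed to terminate");
        break;
      }
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;
      dst(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Closest pair between two point sets; returns (i in A, j in B, distance),
// indices 1-based. Used to bridge disconnected graph components.
// [[Rcpp::export(name = ".closest_pair_cpp")]]
NumericVector closest_pair_cpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  int bi = -1, bj = -1;
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = b(j, 0) - ax, dy = b(j, 1) - ay, dz = b(j, 2) - az;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = i; bj = j; }
    }
  }
  return NumericVector::create(bi + 1, bj + 1, std::sqrt(best));
}
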