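// Density-based clustering (DBSCAN) with a uniform-grid spatial index.
// Points are binned into cells of edge eps; neighbour queries scan the
// 27-cell neighbourhood. Returns 0 for noise, 1..k for clusters.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

static inline int64_t cell_id(int ix, int iy, int iz) {
  // pack three 21-bit signed cell coordinates into one 64-bit key
  const int64_t B = 1 << 20;
  return (((int64_t)ix + B) << 42) | (((int64_t)iy + B) << 21) |
         ((int64_t)iz + B);
}

// [[Rcpp::export(name = ".dbscan_grid")]]
IntegerVector dbscan_grid(NumericMatrix coords, double eps, int min_pts) {
  const int n = coords.nrow();
  IntegerVector labels(n, NA_INTEGER);
  if (n == 0) return labels;
  const double eps2 = eps * eps;

  std::vector<int> cx(n), cy(n), cz(n);
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(coords(i, 0) / eps);
    cy[i] = (int)std::floor(coords(i, 1) / eps);
    cz[i] = (int)std::floor(coords(i, 2) / eps);
    grid[cell_id(cx[i], cy[i], cz[i])].push_back(i);
  }

  std::vector<int> nb;
  nb.reserve(256);
  auto neighbours = [&](int i) {
    nb.clear();
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_id(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = coords(j, 0) - x;
            const double ddy = coords(j, 1) - y;
            const double ddz = coords(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz <= eps2) nb.push_back(j);
          }
        }
  };

  // pass 1: core flags
  std::vector<bool> core(n, false);
  for (int i = 0; i < n; ++i) {
    neighbours(i);
    core[i] = (int)nb.size() >= min_pts;
  }

  // pass 2: expand clusters from core points (border points join the
  // first cluster that reaches them, noise may be adopted as border)
  int cl = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != NA_INTEGER) continue;
    if (!core[i]) { labels[i] = 0; continue; }
    ++cl;
    labels[i] = cl;
    q.push(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      if (!core[p]) continue;
      neighbours(p);
      for (int j : nb) {
        if (labels[j] == NA_INTEGER || labels[j] == 0) {
          labels[j] = cl;
          if (core[j]) q.push(j);
        }
      }
    }
  }
  return labels;
}
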