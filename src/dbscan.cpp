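#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Grid-indexed DBSCAN on 2-D points. Cells have side eps, so all neighbors
// of a point lie in its 3x3 cell block. Labels: 0 = noise, 1..k = clusters.
// A point is core if it has >= min_pts neighbors within eps (itself
// included). Border points join the first cluster that reaches them.

static inline std::int64_t cell_key(int cx, int cy) {
  return (static_cast<std::int64_t>(cx) << 32) ^
         static_cast<std::int64_t>(static_cast<std::uint32_t>(cy));
}

// [[Rcpp::export]]
IntegerVector dbscan_labels(NumericVector x, NumericVector y, double eps,
                            int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  const double eps2 = eps * eps;

  std::unordered_map<std::int64_t, std::vector<int>> grid;
  grid.reserve(static_cast<size_t>(n));
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int>(std::floor(x[i] / eps));
    cy[i] = static_cast<int>(std::floor(y[i] / eps));
    grid[cell_key(cx[i], cy[i])].push_back(i);
  }

  std::vector<int> nbr;
  auto region_query = [&](int i, std::vector<int> &out) {
    out.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cell_key(cx[i] + dx, cy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          const double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
    }
  };

  std::vector<bool> visited(n, false);
  std::vector<int> seeds;
  int next_cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    region_query(i, nbr);
    if (static_cast<int>(nbr.size()) < min_pts) continue; // noise (may be claimed later)
    ++next_cluster;
    labels[i] = next_cluster;
    seeds.assign(nbr.begin(), nbr.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      const int j = seeds[s];
      if (labels[j] == 0) labels[j] = next_cluster;
      if (visited[j]) continue;
      visited[j] = true;
      region_query(j, nbr);
      if (static_cast<int>(nbr.size()) >= min_pts) {
        for (int k : nbr) {
          if (!visited[k] || labels[k] == 0) seeds.push_back(k);
        }
      }
    }
  }
  return labels;
}
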