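#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// A* shortest path on the voxel grid for the gap-reconnection cost
//
//   cost(p) = sum_{i=1..#p} (1 - den(p_i)) * f_s
//           + sum_{i=2..#p} dist(p_{i-1}, p_i)
//
// where dist is the center-to-center distance under `spacing` (pass
// c(1,1,1) for voxel units) and den is the normalized density in [0,1].
// The path starts on any voxel of `source` and ends on the first-reached
// voxel of `target`; `forbidden` voxels are never entered. `heuristic`
// is a per-voxel lower bound on the remaining cost (e.g. the Euclidean
// distance to the target set; the density term is >= 0, so that bound is
// admissible). Ties are broken deterministically by (f, voxel index).

struct QEnt {
  double f;
  double g;
  R_xlen_t v;
};
struct QCmp {
  bool operator()(const QEnt& a, const QEnt& b) const {
    if (a.f != b.f) return a.f > b.f;
    return a.v > b.v;
  }
};

// [[Rcpp::export]]
List cpp_astar(NumericVector den, IntegerVector dims, LogicalVector source,
               LogicalVector target, LogicalVector forbidden, double fs,
               NumericVector spacing, int connectivity,
               NumericVector heuristic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<int> dx, dy, dz;
  std::vector<double> step;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
        double sx = cx * spacing[0], sy = cy * spacing[1], sz = cz * spacing[2];
        step.push_back(std::sqrt(sx * sx + sy * sy + sz * sz));
      }
  const int ndir = (int)dx.size();

  std::vector<double> g(n, INF);
  std::vector<R_xlen_t> prev(n, -1);
  std::vector<char> closed(n, 0);
  std::priority_queue<QEnt, std::vector<QEnt>, QCmp> open;

  for (R_xlen_t v = 0; v < n; ++v) {
    if (source[v] && !forbidden[v]) {
      double gv = (1.0 - den[v]) * fs;
      g[v] = gv;
      open.push({gv + heuristic[v], gv, v});
    }
  }

  R_xlen_t goal = -1;
  while (!open.empty()) {
    QEnt e = open.top();
    open.pop();
    R_xlen_t v = e.v;
    if (closed[v] || e.g > g[v]) continue;
    closed[v] = 1;
    if (target[v]) { goal = v; break; }
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (int d = 0; d < ndir; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (forbidden[w] || closed[w]) continue;
      double ng = g[v] + step[d] + (1.0 - den[w]) * fs;
      if (ng < g[w]) {
        g[w] = ng;
        prev[w] = v;
        open.push({ng + heuristic[w], ng, w});
      }
    }
  }

  if (goal < 0) return List::create(Named("found") = false);

  std::vector<R_xlen_t> path;
  for (R_xlen_t v = goal; v >= 0; v = prev[v]) {
    path.push_back(v);
    if (prev[v] < 0) break;
  }
  std::reverse(path.begin(), path.end());
  IntegerVector pv((R_xlen_t)path.size());
  for (size_t i = 0; i < path.size(); ++i) pv[i] = (int)(path[i] + 1);
  return List::create(Named("found") = true, Named("path") = pv,
                      Named("cost") = g[goal]);
}
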