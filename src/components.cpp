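#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Linear index convention throughout src/: R arrays with dim c(nx, ny, nz),
// column-major, 0-based idx = x + nx * (y + ny * z).

static inline void build_offsets(int connectivity,
                                 std::vector<int>& dx,
                                 std::vector<int>& dy,
                                 std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> dx, dy, dz;
  build_offsets(connectivity, dx, dy, dz);
  const int ndir = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int label = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || out[seed] != 0) continue;
    ++label;
    stack.push_back(seed);
    out[seed] = label;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < ndir; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && out[w] == 0) {
          out[w] = label;
          stack.push_back(w);
        }
      }
    }
  }
  out.attr("dim") = dims;
  out.attr("n_components") = label;
  return out;
}

// Voxels of `mask` that are `connectivity`-adjacent to a voxel of `other`.
// [[Rcpp::export]]
LogicalVector cpp_adjacent_mask(LogicalVector mask, LogicalVector other,
                                IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, FALSE);
  std::vector<int> dx, dy, dz;
  build_offsets(connectivity, dx, dy, dz);
  const int ndir = (int)dx.size();
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (int d = 0; d < ndir; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (other[w]) { out[v] = TRUE; break; }
    }
  }
  out.attr("dim") = dims;
  return out;
}
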