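#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding (Meyer): seeds are
// popped in order of increasing relief value; each masked voxel takes
// the label of the first front that reaches it. Ties are broken by
// insertion order, which makes the result deterministic given seeds.

struct WEnt {
  double prio;
  long long order;
  R_xlen_t v;
  int label;
};
struct WCmp {
  bool operator()(const WEnt& a, const WEnt& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_marker_watershed(NumericVector relief, IntegerVector dims,
                                   IntegerVector markers, LogicalVector mask,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int ndir = (int)dx.size();

  std::priority_queue<WEnt, std::vector<WEnt>, WCmp> pq;
  long long order = 0;
  for (R_xlen_t v = 0; v < n; ++v)
    if (markers[v] > 0 && mask[v]) pq.push({relief[v], order++, v, markers[v]});

  while (!pq.empty()) {
    WEnt e = pq.top();
    pq.pop();
    if (out[e.v] != 0) continue;
    out[e.v] = e.label;
    int x = (int)(e.v % nx);
    int y = (int)((e.v / nx) % ny);
    int z = (int)(e.v / ((R_xlen_t)nx * ny));
    for (int d = 0; d < ndir; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[w] && out[w] == 0) pq.push({relief[w], order++, w, e.label});
    }
  }
  out.attr("dim") = dims;
  return out;
}
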