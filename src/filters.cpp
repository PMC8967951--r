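#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Reflect an index into [0, n) (symmetric reflection, edge duplicated:
// -1 -> 0, -2 -> 1, n -> n-1, ...).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Median filter over a box window. Even window sizes are anchored with
// the extra extent toward the +axis: a window of size w covers offsets
// [-(w-1)/2, w/2] (integer division). Reflective boundary handling.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector x, IntegerVector dims,
                                IntegerVector window) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int wx = window[0], wy = window[1], wz = window[2];
  const int lx = -((wx - 1) / 2), hx = wx / 2;
  const int ly = -((wy - 1) / 2), hy = wy / 2;
  const int lz = -((wz - 1) / 2), hz = wz / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf((size_t)wx * wy * wz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        size_t m = 0;
        for (int dz = lz; dz <= hz; ++dz) {
          int zz = reflect(z + dz, nz);
          for (int dy = ly; dy <= hy; ++dy) {
            int yy = reflect(y + dy, ny);
            for (int dx = lx; dx <= hx; ++dx) {
              int xr = reflect(xx + dx, nx);
              buf[m++] = x[xr + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            }
          }
        }
        // median convention: for even counts take the lower middle after
        // sorting, i.e. element (m-1)/2 (order statistic), so output values
        // always occur in the input
        size_t mid = (m - 1) / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + m);
        out[xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = buf[mid];
      }
  out.attr("dim") = dims;
  return out;
}

static void conv1d_axis(std::vector<double>& g, int nx, int ny, int nz,
                        const std::vector<double>& k, int axis) {
  int r = ((int)k.size() - 1) / 2;
  std::vector<double> line, res;
  int n_axis = axis == 0 ? nx : (axis == 1 ? ny : nz);
  line.resize(n_axis);
  res.resize(n_axis);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)nx * (a + (R_xlen_t)ny * b);
      else if (axis == 1) base = a + (R_xlen_t)nx * ny * (R_xlen_t)b;
      else base = a + (R_xlen_t)nx * b;
      for (int i = 0; i < n_axis; ++i) line[i] = g[base + stride * i];
      for (int i = 0; i < n_axis; ++i) {
        double s = 0;
        for (int j = -r; j <= r; ++j)
          s += k[j + r] * line[reflect(i + j, n_axis)];
        res[i] = s;
      }
      for (int i = 0; i < n_axis; ++i) g[base + stride * i] = res[i];
    }
}

// Separable Gaussian blur; sigma given in voxels per axis. sigma <= 0 on
// an axis skips that axis. Reflective boundaries; kernels normalized.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dims,
                                NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = x[i];
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      sum += k[j + r];
    }
    for (double& v : k) v /= sum;
    conv1d_axis(g, nx, ny, nz, k, axis);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}
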