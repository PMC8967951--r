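#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Triangle / axis-aligned-box overlap via the separating axis theorem
// (13 axes: 3 box normals, 1 triangle normal, 9 edge cross products).
// Touching counts as overlap; the caller realizes the half-open voxel
// convention by shrinking the box on its +faces by a small epsilon.

static inline void cross3(const double a[3], const double b[3], double r[3]) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static bool axis_separates(const double axis[3], const double v0[3],
                           const double v1[3], const double v2[3],
                           const double half[3]) {
  double p0 = dot3(axis, v0), p1 = dot3(axis, v1), p2 = dot3(axis, v2);
  double r = half[0] * std::fabs(axis[0]) + half[1] * std::fabs(axis[1]) +
             half[2] * std::fabs(axis[2]);
  double mn = std::min(p0, std::min(p1, p2));
  double mx = std::max(p0, std::max(p1, p2));
  return mn > r || mx < -r;
}

static bool tri_box_overlap(const double center[3], const double half[3],
                            const double t0[3], const double t1[3],
                            const double t2[3]) {
  double v0[3], v1[3], v2[3];
  for (int i = 0; i < 3; ++i) {
    v0[i] = t0[i] - center[i];
    v1[i] = t1[i] - center[i];
    v2[i] = t2[i] - center[i];
  }
  // box normals
  for (int i = 0; i < 3; ++i) {
    double mn = std::min(v0[i], std::min(v1[i], v2[i]));
    double mx = std::max(v0[i], std::max(v1[i], v2[i]));
    if (mn > half[i] || mx < -half[i]) return false;
  }
  double e0[3], e1[3], e2[3];
  for (int i = 0; i < 3; ++i) {
    e0[i] = v1[i] - v0[i];
    e1[i] = v2[i] - v1[i];
    e2[i] = v0[i] - v2[i];
  }
  // triangle normal
  double nrm[3];
  cross3(e0, e1, nrm);
  if (axis_separates(nrm, v0, v1, v2, half)) return false;
  // 9 edge cross products
  const double* edges[3] = {e0, e1, e2};
  const double axes_unit[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double ax[3];
  for (int e = 0; e < 3; ++e)
    for (int u = 0; u < 3; ++u) {
      cross3(axes_unit[u], edges[e], ax);
      if (std::fabs(ax[0]) + std::fabs(ax[1]) + std::fabs(ax[2]) < 1e-300)
        continue;  // parallel, degenerate axis
      if (axis_separates(ax, v0, v1, v2, half)) return false;
    }
  return true;
}

// Mark every voxel whose half-open physical box [i,i+1) (x) voxel_size
// + origin intersects at least one mesh triangle. verts: n x 3 (um),
// faces: m x 3 (1-based vertex indices).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_mesh(NumericMatrix verts, IntegerMatrix faces,
                                 NumericVector origin, NumericVector vsize,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz, FALSE);
  const double eps[3] = {1e-7 * vsize[0], 1e-7 * vsize[1], 1e-7 * vsize[2]};
  double half[3], t0[3], t1[3], t2[3], center[3];
  // half-open convention: shrink the box symmetrically off its +faces
  for (int i = 0; i < 3; ++i) half[i] = 0.5 * vsize[i] - 0.5 * eps[i];

  for (int f = 0; f < faces.nrow(); ++f) {
    int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    for (int c = 0; c < 3; ++c) {
      t0[c] = verts(i0, c);
      t1[c] = verts(i1, c);
      t2[c] = verts(i2, c);
    }
    int lo[3], hi[3];
    for (int c = 0; c < 3; ++c) {
      double mn = std::min(t0[c], std::min(t1[c], t2[c]));
      double mx = std::max(t0[c], std::max(t1[c], t2[c]));
      lo[c] = (int)std::floor((mn - origin[c]) / vsize[c]) - 1;
      hi[c] = (int)std::floor((mx - origin[c]) / vsize[c]) + 1;
      int nmax = c == 0 ? nx : (c == 1 ? ny : nz);
      lo[c] = std::max(lo[c], 0);
      hi[c] = std::min(hi[c], nmax - 1);
    }
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int x = lo[0]; x <= hi[0]; ++x) {
          R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (out[v]) continue;
          center[0] = origin[0] + (x + 0.5) * vsize[0] - 0.5 * eps[0];
          center[1] = origin[1] + (y + 0.5) * vsize[1] - 0.5 * eps[1];
          center[2] = origin[2] + (z + 0.5) * vsize[2] - 0.5 * eps[2];
          if (tri_box_overlap(center, half, t0, t1, t2)) out[v] = TRUE;
        }
  }
  out.attr("dim") = dims;
  return out;
}
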