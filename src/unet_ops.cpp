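#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout: activations are R arrays dim c(nx, ny, nz, C)
// (column-major, x fastest, channel last). Convolution weights are
// arrays dim c(kx, ky, kz, cin, cout); transposed-convolution weights
// dim c(fx, fy, fz, cin, cout) with kernel size == stride == f.
// Convolutions use zero padding `pad` per axis (0 = valid, (k-1)/2 = same).

static inline int reflect_ix(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// columns layout: N x K (output voxel fastest), so fills and reads run
// over contiguous memory and the GEMM results land in R's array layout.
// reflect != 0 pads convolutions reflectively instead of with zeros.
static arma::mat im2col(const double* x, const int* xd, const int* kd,
                        const int* pad, int ox, int oy, int oz, int reflect) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int kx = kd[0], ky = kd[1], kz = kd[2];
  const long long N = (long long)ox * oy * oz;
  const long long K = (long long)kx * ky * kz * cin;
  arma::mat col(N, K, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + (long long)nx * ny * nz * ci;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          long long k = dx + (long long)kx * (dy + (long long)ky * (dz + (long long)kz * ci));
          double* dest = col.colptr(k);
          int x0 = std::max(0, pad[0] - dx);
          int x1 = std::min(ox - 1, nx - 1 + pad[0] - dx);
          for (int z = 0; z < oz; ++z) {
            int zz = z + dz - pad[2];
            if (zz < 0 || zz >= nz) {
              if (!reflect) continue;
              zz = reflect_ix(zz, nz);
            }
            for (int y = 0; y < oy; ++y) {
              int yy = y + dy - pad[1];
              if (yy < 0 || yy >= ny) {
                if (!reflect) continue;
                yy = reflect_ix(yy, ny);
              }
              long long nbase = (long long)ox * (y + (long long)oy * z);
              const double* src = xc + (long long)nx * (yy + (long long)ny * zz)
                                  + (dx - pad[0]);
              for (int xp = x0; xp <= x1; ++xp)
                dest[nbase + xp] = src[xp];
              if (reflect) {
                for (int xp = 0; xp < x0; ++xp)
                  dest[nbase + xp] =
                    xc[reflect_ix(xp + dx - pad[0], nx) +
                       (long long)nx * (yy + (long long)ny * zz)];
                for (int xp = x1 + 1; xp < ox; ++xp)
                  dest[nbase + xp] =
                    xc[reflect_ix(xp + dx - pad[0], nx) +
                       (long long)nx * (yy + (long long)ny * zz)];
              }
            }
          }
        }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b, IntegerVector pad,
                             int reflect) {
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], cin = wdim[3],
            cout = wdim[4];
  const int ox = xdim[0] + 2 * pad[0] - kx + 1;
  const int oy = xdim[1] + 2 * pad[1] - ky + 1;
  const int oz = xdim[2] + 2 * pad[2] - kz + 1;
  const long long K = (long long)kx * ky * kz * cin;
  const long long N = (long long)ox * oy * oz;
  int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  int kd[3] = {kx, ky, kz};
  int pd[3] = {pad[0], pad[1], pad[2]};
  arma::mat col = im2col(x.begin(), xd, kd, pd, ox, oy, oz, reflect);
  arma::mat W(const_cast<double*>(w.begin()), K, cout, false, true);
  NumericVector out(N * cout);
  arma::mat Y(out.begin(), N, cout, false, true);
  Y = col * W;  // N x cout, lands directly in the output layout
  for (int c = 0; c < cout; ++c) {
    double bc = b[c];
    double* o = out.begin() + N * c;
    for (long long i = 0; i < N; ++i) o[i] += bc;
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    IntegerVector wdim, NumericVector dy, IntegerVector ydim,
                    IntegerVector pad, int reflect) {
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], cin = wdim[3],
            cout = wdim[4];
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2];
  const long long K = (long long)kx * ky * kz * cin;
  const long long N = (long long)ox * oy * oz;
  int xd[4] = {xdim[0], xdim[1], xdim[2], xdim[3]};
  int kd[3] = {kx, ky, kz};
  int pd[3] = {pad[0], pad[1], pad[2]};
  arma::mat col = im2col(x.begin(), xd, kd, pd, ox, oy, oz, reflect);
  arma::mat dY(const_cast<double*>(dy.begin()), N, cout, false, true);

  NumericVector dwv(K * cout);
  arma::mat dW(dwv.begin(), K, cout, false, true);
  dW = col.t() * dY;  // K x cout, matches the weight layout
  dwv.attr("dim") = wdim;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat W(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat dcol = dY * W.t();  // N x K

  // col2im: accumulate dcol back into dx
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  NumericVector dx((long long)nx * ny * nz * cin);
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx.begin() + (long long)nx * ny * nz * ci;
    for (int dz = 0; dz < kz; ++dz)
      for (int dyk = 0; dyk < ky; ++dyk)
        for (int dxk = 0; dxk < kx; ++dxk) {
          long long k = dxk + (long long)kx * (dyk + (long long)ky * (dz + (long long)kz * ci));
          const double* src = dcol.colptr(k);
          int x0 = std::max(0, pad[0] - dxk);
          int x1 = std::min(ox - 1, nx - 1 + pad[0] - dxk);
          for (int z = 0; z < oz; ++z) {
            int zz = z + dz - pad[2];
            if (zz < 0 || zz >= nz) {
              if (!reflect) continue;
              zz = reflect_ix(zz, nz);
            }
            for (int y = 0; y < oy; ++y) {
              int yy = y + dyk - pad[1];
              if (yy < 0 || yy >= ny) {
                if (!reflect) continue;
                yy = reflect_ix(yy, ny);
              }
              long long nbase = (long long)ox * (y + (long long)oy * z);
              double* dest = xc + (long long)nx * (yy + (long long)ny * zz)
                             + (dxk - pad[0]);
              for (int xp = x0; xp <= x1; ++xp)
                dest[xp] += src[nbase + xp];
              if (reflect) {
                for (int xp = 0; xp < x0; ++xp)
                  xc[reflect_ix(xp + dxk - pad[0], nx) +
                     (long long)nx * (yy + (long long)ny * zz)] +=
                    src[nbase + xp];
                for (int xp = x1 + 1; xp < ox; ++xp)
                  xc[reflect_ix(xp + dxk - pad[0], nx) +
                     (long long)nx * (yy + (long long)ny * zz)] +=
                    src[nbase + xp];
              }
            }
          }
        }
  }
  dx.attr("dim") = xdim;
  return List::create(Named("dw") = dwv,
                      Named("db") = NumericVector(db.begin(), db.end()),
                      Named("dx") = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim, IntegerVector f) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  const int fx = f[0], fy = f[1], fz = f[2];
  const int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  const long long N = (long long)ox * oy * oz;
  NumericVector out(N * C);
  IntegerVector amax(N * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long long)nx * ny * nz * c;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xp = 0; xp < ox; ++xp) {
          double best = -1e300;
          long long bidx = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                long long i = (xp * fx + dx) +
                              (long long)nx * ((y * fy + dy) +
                                               (long long)ny * (z * fz + dz));
                if (xc[i] > best) { best = xc[i]; bidx = i; }
              }
          long long o = xp + (long long)ox * (y + (long long)oy * z) + N * c;
          out[o] = best;
          amax[o] = (int)(bidx + (long long)nx * ny * nz * c);
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(Named("out") = out, Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dx((long long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (long long i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upconv_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int fx = wdim[0], fy = wdim[1], fz = wdim[2], cout = wdim[4];
  const int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  const long long NO = (long long)ox * oy * oz;
  NumericVector out(NO * cout);
  for (int co = 0; co < cout; ++co) {
    double* oc = out.begin() + NO * co;
    for (long long i = 0; i < NO; ++i) oc[i] = b[co];
  }
  for (int co = 0; co < cout; ++co) {
    double* oc = out.begin() + NO * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = x.begin() + (long long)nx * ny * nz * ci;
      for (int dz = 0; dz < fz; ++dz)
        for (int dy = 0; dy < fy; ++dy)
          for (int dx = 0; dx < fx; ++dx) {
            double wv = w[dx + (long long)fx * (dy + (long long)fy *
                          (dz + (long long)fz * (ci + (long long)cin * co)))];
            if (wv == 0) continue;
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y)
                for (int xp = 0; xp < nx; ++xp) {
                  long long o = (xp * fx + dx) +
                                (long long)ox * ((y * fy + dy) +
                                                 (long long)oy * (z * fz + dz));
                  oc[o] += wv * xc[xp + (long long)nx * (y + (long long)ny * z)];
                }
          }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    IntegerVector wdim, NumericVector dy) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const int fx = wdim[0], fy = wdim[1], fz = wdim[2], cout = wdim[4];
  const int ox = nx * fx, oy = ny * fy, oz = nz * fz;
  const long long NO = (long long)ox * oy * oz;
  NumericVector dw(w.size());
  NumericVector db(cout);
  NumericVector dx(x.size());
  for (int co = 0; co < cout; ++co) {
    const double* gc = dy.begin() + NO * co;
    double s = 0;
    for (long long i = 0; i < NO; ++i) s += gc[i];
    db[co] = s;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = x.begin() + (long long)nx * ny * nz * ci;
      double* dxc = dx.begin() + (long long)nx * ny * nz * ci;
      for (int dz = 0; dz < fz; ++dz)
        for (int dyk = 0; dyk < fy; ++dyk)
          for (int dxk = 0; dxk < fx; ++dxk) {
            long long widx = dxk + (long long)fx * (dyk + (long long)fy *
                             (dz + (long long)fz * (ci + (long long)cin * co)));
            double wv = w[widx], acc = 0;
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y)
                for (int xp = 0; xp < nx; ++xp) {
                  long long o = (xp * fx + dxk) +
                                (long long)ox * ((y * fy + dyk) +
                                                 (long long)oy * (z * fz + dz));
                  long long i = xp + (long long)nx * (y + (long long)ny * z);
                  acc += gc[o] * xc[i];
                  dxc[i] += gc[o] * wv;
                }
            dw[widx] += acc;
          }
    }
  }
  dw.attr("dim") = wdim;
  dx.attr("dim") = xdim;
  return List::create(Named("dw") = dw, Named("db") = db, Named("dx") = dx);
}
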