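// Low-level volumetric network operations.
//
// Tensor layout: one sample per column. Within a column the flat index of
// voxel (c, z, y, x) is ((c*D + z)*H + y)*W + x (x fastest). All ops are
// deterministic and single-threaded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// colsT has one column per (c, kz, ky, kx) patch offset and one row per
// output voxel (x fastest): writes are contiguous down each column.
// Convolutions run in single precision internally (inputs/outputs stay
// double at the R boundary): sgemm and halved bandwidth dominate the cost.
static void im2col(const float* x, int C, int D, int H, int W,
                   int k, int sz, int sy, int sx, int pad, arma::fmat& colsT) {
  const int Do = out_extent(D, k, sz, pad);
  const int Ho = out_extent(H, k, sy, pad);
  const int Wo = out_extent(W, k, sx, pad);
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = ((c * k + kz) * k + ky) * k + kx;
          float* dst = colsT.colptr(col);
          for (int zo = 0; zo < Do; ++zo) {
            const int z = zo * sz - pad + kz;
            for (int yo = 0; yo < Ho; ++yo) {
              const int y = yo * sy - pad + ky;
              if (z < 0 || z >= D || y < 0 || y >= H) {
                std::memset(dst, 0, sizeof(float) * Wo);
                dst += Wo;
                continue;
              }
              const float* src = x + ((size_t)(c * D + z) * H + y) * W;
              if (sx == 1 && pad <= kx && kx - pad + Wo <= W) {
                std::memcpy(dst, src + kx - pad, sizeof(float) * Wo);
                dst += Wo;
              } else {
                for (int xo = 0; xo < Wo; ++xo) {
                  const int xx = xo * sx - pad + kx;
                  *dst++ = (xx < 0 || xx >= W) ? 0.0 : src[xx];
                }
              }
            }
          }
        }
  }
}

static void col2im_add(const arma::fmat& colsT, int C, int D, int H, int W,
                       int k, int sz, int sy, int sx, int pad, float* dx) {
  const int Do = out_extent(D, k, sz, pad);
  const int Ho = out_extent(H, k, sy, pad);
  const int Wo = out_extent(W, k, sx, pad);
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = ((c * k + kz) * k + ky) * k + kx;
          const float* src = colsT.colptr(col);
          for (int zo = 0; zo < Do; ++zo) {
            const int z = zo * sz - pad + kz;
            if (z < 0 || z >= D) { src += (size_t)Ho * Wo; continue; }
            for (int yo = 0; yo < Ho; ++yo) {
              const int y = yo * sy - pad + ky;
              if (y < 0 || y >= H) { src += Wo; continue; }
              float* dstrow = dx + ((size_t)(c * D + z) * H + y) * W;
              for (int xo = 0; xo < Wo; ++xo) {
                const int xx = xo * sx - pad + kx;
                if (xx >= 0 && xx < W) dstrow[xx] += src[xo];
              }
              src += Wo;
            }
          }
        }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fw(const arma::mat& X, const arma::mat& Wm,
                        const arma::vec& b, int C, int D, int H, int W,
                        int k, int sz, int sy, int sx, int pad) {
  const int Do = out_extent(D, k, sz, pad);
  const int Ho = out_extent(H, k, sy, pad);
  const int Wo = out_extent(W, k, sx, pad);
  const int Vo = Do * Ho * Wo;
  const int Cout = Wm.n_rows;
  const int N = X.n_cols;
  arma::mat Y((size_t)Cout * Vo, N);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wt = arma::conv_to<arma::fmat>::from(Wm).t();
  arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
  arma::fmat colsT(Vo, C * k * k * k);
  arma::fmat outT(Vo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col(Xf.colptr(n), C, D, H, W, k, sz, sy, sx, pad, colsT);
    // output layout per column is (v fast within channel), i.e. exactly the
    // column-major storage of the (Vo x Cout) product colsT * Wm'
    outT = colsT * Wt;
    double* y = Y.colptr(n);
    for (int c = 0; c < Cout; ++c) {
      const float* oc = outT.colptr(c);
      const double bc = bf[c];
      for (int v = 0; v < Vo; ++v) y[(size_t)c * Vo + v] = oc[v] + bc;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const arma::mat& X, const arma::mat& Wm, const arma::mat& dY,
                   int C, int D, int H, int W,
                   int k, int sz, int sy, int sx, int pad, bool need_dx) {
  const int Do = out_extent(D, k, sz, pad);
  const int Ho = out_extent(H, k, sy, pad);
  const int Wo = out_extent(W, k, sx, pad);
  const int Vo = Do * Ho * Wo;
  const int Cout = Wm.n_rows;
  const int N = X.n_cols;
  arma::fmat dWf(Cout, Wm.n_cols, arma::fill::zeros);
  arma::fvec dbf(Cout, arma::fill::zeros);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat dXf;
  if (need_dx) dXf.zeros(X.n_rows, N);
  arma::fmat colsT(Vo, C * k * k * k);
  arma::fmat dcolsT(Vo, C * k * k * k);
  for (int n = 0; n < N; ++n) {
    // dY column has layout c*Vo + v: a (Vo x Cout) matrix view
    arma::fmat dys(dYf.colptr(n), Vo, Cout, false, true);
    im2col(Xf.colptr(n), C, D, H, W, k, sz, sy, sx, pad, colsT);
    dWf += dys.t() * colsT;
    dbf += arma::sum(dys, 0).t();
    if (need_dx) {
      dcolsT = dys * Wf;                 // Vo x (C*k^3)
      col2im_add(dcolsT, C, D, H, W, k, sz, sy, sx, pad, dXf.colptr(n));
    }
  }
  arma::mat dX;
  if (need_dx) dX = arma::conv_to<arma::mat>::from(dXf);
  return List::create(_["dX"] = dX,
                      _["dW"] = arma::conv_to<arma::mat>::from(dWf),
                      _["db"] = arma::conv_to<arma::vec>::from(dbf));
}

// [[Rcpp::export]]
List cpp_maxpool3d_fw(const arma::mat& X, int C, int D, int H, int W,
                      int k, int s, int pad) {
  const int Do = out_extent(D, k, s, pad);
  const int Ho = out_extent(H, k, s, pad);
  const int Wo = out_extent(W, k, s, pad);
  const int Vo = Do * Ho * Wo;
  const int N = X.n_cols;
  arma::mat Y((size_t)C * Vo, N);
  arma::umat idx((size_t)C * Vo, N);
  for (int n = 0; n < N; ++n) {
    const double* x = X.colptr(n);
    double* y = Y.colptr(n);
    arma::uword* id = idx.colptr(n);
    for (int c = 0; c < C; ++c) {
      for (int zo = 0; zo < Do; ++zo)
        for (int yo = 0; yo < Ho; ++yo)
          for (int xo = 0; xo < Wo; ++xo) {
            double best = -std::numeric_limits<double>::infinity();
            size_t besti = 0;
            for (int kz = 0; kz < k; ++kz) {
              const int z = zo * s - pad + kz;
              if (z < 0 || z >= D) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int yy = yo * s - pad + ky;
                if (yy < 0 || yy >= H) continue;
                for (int kx = 0; kx < k; ++kx) {
                  const int xx = xo * s - pad + kx;
                  if (xx < 0 || xx >= W) continue;
                  const size_t ii = ((size_t)(c * D + z) * H + yy) * W + xx;
                  if (x[ii] > best) { best = x[ii]; besti = ii; }
                }
              }
            }
            const size_t oi = (size_t)c * Vo + ((size_t)(zo * Ho + yo) * Wo + xo);
            y[oi] = best;
            id[oi] = besti;
          }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool3d_bw(const arma::mat& dY, const arma::umat& idx,
                           int in_len) {
  const int N = dY.n_cols;
  arma::mat dX(in_len, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* dy = dY.colptr(n);
    const arma::uword* id = idx.colptr(n);
    double* dx = dX.colptr(n);
    for (size_t i = 0; i < dY.n_rows; ++i) dx[id[i]] += dy[i];
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool3d_fw(const arma::mat& X, int C, int D, int H, int W,
                           int k, int s) {
  // kernel clamped per axis so extents smaller than k still pool over what
  // exists (adaptive behavior; a no-op at the production shapes)
  const int kD = std::min(k, D), kH = std::min(k, H), kW = std::min(k, W);
  const int Do = (D - kD) / s + 1, Ho = (H - kH) / s + 1, Wo = (W - kW) / s + 1;
  const int Vo = Do * Ho * Wo;
  const int N = X.n_cols;
  const double inv = 1.0 / (kD * kH * kW);
  arma::mat Y((size_t)C * Vo, N);
  for (int n = 0; n < N; ++n) {
    const double* x = X.colptr(n);
    double* y = Y.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int zo = 0; zo < Do; ++zo)
        for (int yo = 0; yo < Ho; ++yo)
          for (int xo = 0; xo < Wo; ++xo) {
            double acc = 0.0;
            for (int kz = 0; kz < kD; ++kz)
              for (int ky = 0; ky < kH; ++ky)
                for (int kx = 0; kx < kW; ++kx)
                  acc += x[((size_t)(c * D + zo * s + kz) * H + yo * s + ky) * W
                           + xo * s + kx];
            y[(size_t)c * Vo + ((size_t)(zo * Ho + yo) * Wo + xo)] = acc * inv;
          }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool3d_bw(const arma::mat& dY, int C, int D, int H, int W,
                           int k, int s) {
  const int kD = std::min(k, D), kH = std::min(k, H), kW = std::min(k, W);
  const int Do = (D - kD) / s + 1, Ho = (H - kH) / s + 1, Wo = (W - kW) / s + 1;
  const int Vo = Do * Ho * Wo;
  const int N = dY.n_cols;
  const double inv = 1.0 / (kD * kH * kW);
  arma::mat dX((size_t)C * D * H * W, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* dy = dY.colptr(n);
    double* dx = dX.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int zo = 0; zo < Do; ++zo)
        for (int yo = 0; yo < Ho; ++yo)
          for (int xo = 0; xo < Wo; ++xo) {
            const double g = dy[(size_t)c * Vo + ((size_t)(zo * Ho + yo) * Wo + xo)] * inv;
            for (int kz = 0; kz < kD; ++kz)
              for (int ky = 0; ky < kH; ++ky)
                for (int kx = 0; kx < kW; ++kx)
                  dx[((size_t)(c * D + zo * s + kz) * H + yo * s + ky) * W
                     + xo * s + kx] += g;
          }
  }
  return dX;
}

// Batch normalization over channels; statistics pooled over the spatial
// volume V and the batch. Optionally fuses a ReLU on the output.
// [[Rcpp::export]]
List cpp_bn_fw(const arma::mat& X, int C, int V,
               const arma::vec& gamma, const arma::vec& beta,
               arma::vec rmean, arma::vec rvar,
               double momentum, double eps, bool training, bool relu) {
  const int N = X.n_cols;
  arma::vec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* x = X.colptr(n) + (size_t)c * V;
        for (int v = 0; v < V; ++v) acc += x[v];
      }
      mu[c] = acc / ((double)V * N);
      double acc2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* x = X.colptr(n) + (size_t)c * V;
        for (int v = 0; v < V; ++v) { const double d = x[v] - mu[c]; acc2 += d * d; }
      }
      var[c] = acc2 / ((double)V * N);
      rmean[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      rvar[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  } else {
    mu = rmean; var = rvar;
  }
  arma::mat Y(X.n_rows, N);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mu[c];
    for (int n = 0; n < N; ++n) {
      const double* x = X.colptr(n) + (size_t)c * V;
      double* y = Y.colptr(n) + (size_t)c * V;
      for (int v = 0; v < V; ++v) {
        double val = g * (x[v] - m) * istd + b;
        if (relu && val < 0) val = 0;
        y[v] = val;
      }
    }
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["var"] = var,
                      _["rmean"] = rmean, _["rvar"] = rvar);
}

// [[Rcpp::export]]
List cpp_bn_bw(const arma::mat& X, const arma::mat& dYin, const arma::mat& Y,
               const arma::vec& gamma, const arma::vec& mu, const arma::vec& var,
               double eps, bool training, bool relu) {
  const int N = dYin.n_cols;
  const int C = gamma.n_elem;
  const int V = X.n_rows / C;
  const double m = (double)V * N;
  arma::mat dX(X.n_rows, N);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], mc = mu[c];
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x = X.colptr(n) + (size_t)c * V;
      const double* dy = dYin.colptr(n) + (size_t)c * V;
      const double* yy = Y.colptr(n) + (size_t)c * V;
      for (int v = 0; v < V; ++v) {
        double d = dy[v];
        if (relu && yy[v] <= 0) d = 0;
        const double xh = (x[v] - mc) * istd;
        sum_dy += d;
        sum_dy_xhat += d * xh;
      }
    }
    dgamma[c] = sum_dy_xhat;
    dbeta[c] = sum_dy;
    for (int n = 0; n < N; ++n) {
      const double* x = X.colptr(n) + (size_t)c * V;
      const double* dy = dYin.colptr(n) + (size_t)c * V;
      const double* yy = Y.colptr(n) + (size_t)c * V;
      double* dx = dX.colptr(n) + (size_t)c * V;
      for (int v = 0; v < V; ++v) {
        double d = dy[v];
        if (relu && yy[v] <= 0) d = 0;
        const double xh = (x[v] - mc) * istd;
        if (training) {
          dx[v] = g * istd * (d - sum_dy / m - xh * sum_dy_xhat / m);
        } else {
          dx[v] = g * istd * d;
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// In-place helpers for the optimizer path: the volumetric network has tens
// of millions of parameters, and R-level functional updates would copy the
// whole tree every step. Callers guarantee sole ownership of the buffers.

// [[Rcpp::export]]
void cpp_axpy_inplace(Rcpp::NumericVector x, const Rcpp::NumericVector& y) {
  const R_xlen_t n = x.size();
  double* xp = REAL(x);
  const double* yp = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i) xp[i] += yp[i];
}

// [[Rcpp::export]]
void cpp_adam_inplace(Rcpp::NumericVector p, const Rcpp::NumericVector& g,
                      Rcpp::NumericVector m, Rcpp::NumericVector v,
                      double lr, double b1, double b2, double bc1, double bc2,
                      double eps, double wd) {
  const R_xlen_t n = p.size();
  double* pp = REAL(p);
  const double* gp = REAL(g);
  double* mp = REAL(m);
  double* vp = REAL(v);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i] + wd * pp[i];
    mp[i] = b1 * mp[i] + (1 - b1) * gi;
    vp[i] = b2 * vp[i] + (1 - b2) * gi * gi;
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}
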