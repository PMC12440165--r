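// Batched 2-D convolution via im2col + one GEMM across the whole batch, with
// the matching backward pass. Arrays follow R's column-major layout with dims
// (H, W, C, N); kernels are (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill rows [row0, row0 + Ho*Wo) of the batch im2col matrix M for one sample:
// row = row0 + io + Ho*jo, col = ki + kh*(kj + kw*c).
static void im2col_fill(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo, arma::mat& M, size_t row0) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        size_t col = ki + (size_t)kh * (kj + (size_t)kw * c);
        double* Mcol = M.colptr(col) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) {
            for (int io = 0; io < Ho; ++io) Mcol[io + Ho * jo] = 0.0;
            continue;
          }
          const double* xcol = x + (size_t)H * (j + (size_t)W * c);
          for (int io = 0; io < Ho; ++io) {
            int i = io * stride - pad + ki;
            Mcol[io + Ho * jo] = (i >= 0 && i < H) ? xcol[i] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add rows [row0, row0 + Ho*Wo) of dM back onto one sample (col2im).
static void col2im_add(const arma::mat& dM, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx, size_t row0) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        size_t col = ki + (size_t)kh * (kj + (size_t)kw * c);
        const double* Mcol = dM.colptr(col) + row0;
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* xcol = dx + (size_t)H * (j + (size_t)W * c);
          for (int io = 0; io < Ho; ++io) {
            int i = io * stride - pad + ki;
            if (i >= 0 && i < H) xcol[i] += Mcol[io + Ho * jo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_len(H, kh, stride, pad), Wo = out_len(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((size_t)Ho * Wo * N, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n)
    im2col_fill(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride,
                pad, Ho, Wo, M, (size_t)Ho * Wo * n);
  arma::mat Y = M * Wm;                          // (N*Ho*Wo) x Cout
  if (bias.size() == Cout)
    Y.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::copy(Y.colptr(c) + (size_t)Ho * Wo * n,
                Y.colptr(c) + (size_t)Ho * Wo * (n + 1),
                y.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n));
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, bool has_bias, bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  // reassemble dY into the batch-GEMM layout: (N*Ho*Wo) x Cout
  arma::mat dY((size_t)Ho * Wo * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::copy(dy.begin() + (size_t)Ho * Wo * (c + (size_t)Cout * n),
                dy.begin() + (size_t)Ho * Wo * (c + 1 + (size_t)Cout * n),
                dY.colptr(c) + (size_t)Ho * Wo * n);
  arma::mat M((size_t)Ho * Wo * N, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n)
    im2col_fill(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride,
                pad, Ho, Wo, M, (size_t)Ho * Wo * n);
  arma::mat dWm = M.t() * dY;
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  if (need_dx) {
    arma::mat dM = dY * Wm.t();
    for (int n = 0; n < N; ++n)
      col2im_add(dM, H, W, C, kh, kw, stride, pad, Ho, Wo,
                 dx.begin() + (size_t)H * W * C * n, (size_t)Ho * Wo * n);
  }
  if (has_bias) {
    arma::rowvec s = arma::sum(dY, 0);
    for (int c = 0; c < Cout; ++c) db[c] = s[c];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
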