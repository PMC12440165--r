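// Lightweight grayscale image kernels for augmentation and phantom
// rendering: bilinear resize and separable Gaussian blur (replicated edges).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double x = (j + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(x);
    double fx = x - x0;
    int xa = std::min(std::max(x0, 0), W - 1);
    int xb = std::min(std::max(x0 + 1, 0), W - 1);
    for (int i = 0; i < out_h; ++i) {
      double y = (i + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(y);
      double fy = y - y0;
      int ya = std::min(std::max(y0, 0), H - 1);
      int yb = std::min(std::max(y0 + 1, 0), H - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * img(ya, xa) + fx * img(ya, xb)) +
                  fy * ((1 - fx) * img(yb, xa) + fx * img(yb, xb));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)          // vertical pass
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; ++j)          // horizontal pass
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}
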