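// Gather/scatter kernels for the small convolutional networks: 3x3
// same-padding im2col and its transpose, and 2x2 max-pooling with argmax
// bookkeeping. Arrays are column-major with dims (H, W, C, N); the matrix
// produced by im2col3 has one row per output pixel (row = h + H*w + H*W*n)
// and one column per kernel tap (col = kh + 3*kw + 9*c), so convolution is
// a single BLAS matmul against a (9C x F) weight matrix.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int H, int W, int C, int N) {
  NumericMatrix out((R_xlen_t)H * W * N, 9 * C);
  const double* px = x.begin();
  double* pout = out.begin();
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const R_xlen_t col = (R_xlen_t)c * 9 + kw * 3 + kh;
        double* po = pout + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double* plane = px + ((R_xlen_t)n * C + c) * H * W;
          double* pon = po + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - 1;
            double* pow_ = pon + (R_xlen_t)w * H;
            if (ws < 0 || ws >= W) {
              for (int h = 0; h < H; ++h) pow_[h] = 0.0;
            } else {
              const double* pcol = plane + (R_xlen_t)ws * H;
              for (int h = 0; h < H; ++h) {
                const int hs = h + kh - 1;
                pow_[h] = (hs >= 0 && hs < H) ? pcol[hs] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix dcols, int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* pdx = dx.begin();
  const double* pin = dcols.begin();
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const R_xlen_t col = (R_xlen_t)c * 9 + kw * 3 + kh;
        const double* po = pin + col * nrow;
        for (int n = 0; n < N; ++n) {
          double* plane = pdx + ((R_xlen_t)n * C + c) * H * W;
          const double* pon = po + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kw - 1;
            if (ws < 0 || ws >= W) continue;
            const double* pow_ = pon + (R_xlen_t)w * H;
            double* pcol = plane + (R_xlen_t)ws * H;
            for (int h = 0; h < H; ++h) {
              const int hs = h + kh - 1;
              if (hs >= 0 && hs < H) pcol[hs] += pow_[h];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
List maxpool2(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* plane = px + cn * H * W;
    const R_xlen_t base = cn * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        R_xlen_t i00 = (R_xlen_t)(2 * w) * H + 2 * h;
        R_xlen_t best = i00;
        double v = plane[i00];
        if (plane[i00 + 1] > v) { v = plane[i00 + 1]; best = i00 + 1; }
        if (plane[i00 + H] > v) { v = plane[i00 + H]; best = i00 + H; }
        if (plane[i00 + H + 1] > v) { v = plane[i00 + H + 1]; best = i00 + H + 1; }
        py[o] = v;
        pi[o] = (int)(base + best) + 1;  // 1-based into x
        ++o;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double* pdx = dx.begin();
  const double* pdy = dy.begin();
  const int* pi = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pi[i] - 1] += pdy[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
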