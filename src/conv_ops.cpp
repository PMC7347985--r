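#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction / accumulation for 3x3 convolutions with padding 1 on a
// channel-first (C,H,W,N) batch. Patch matrix layout: row (k-1)*C + c holds
// input channel c at kernel offset k in 1..9, k = dw*3 + dh + 1 over
// (dh, dw) in {0,1,2}^2; column h + H*(w-1) + H*W*(n-1) is the output
// position. Out-of-range taps are zero (zero padding).

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, int C, int H, int W, int N) {
  NumericMatrix P(9 * C, (R_xlen_t)H * W * N);
  const double* xp = x.begin();
  double* p = P.begin();
  const R_xlen_t rows = 9 * (R_xlen_t)C;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        R_xlen_t col = ((R_xlen_t)n * W + w) * H + h;
        double* pc = p + col * rows;
        int k = 0;
        for (int dw = 0; dw < 3; ++dw) {
          int sw = w + dw - 1;
          for (int dh = 0; dh < 3; ++dh, ++k) {
            int sh = h + dh - 1;
            double* dst = pc + (R_xlen_t)k * C;
            if (sw < 0 || sw >= W || sh < 0 || sh >= H) {
              std::fill(dst, dst + C, 0.0);
            } else {
              const double* src = xp + (((R_xlen_t)n * W + sw) * H + sh) * C;
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix dP, int C, int H, int W, int N) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* out = dx.begin();
  const double* p = dP.begin();
  const R_xlen_t rows = 9 * (R_xlen_t)C;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        R_xlen_t col = ((R_xlen_t)n * W + w) * H + h;
        const double* pc = p + col * rows;
        int k = 0;
        for (int dw = 0; dw < 3; ++dw) {
          int sw = w + dw - 1;
          for (int dh = 0; dh < 3; ++dh, ++k) {
            int sh = h + dh - 1;
            if (sw < 0 || sw >= W || sh < 0 || sh >= H) continue;
            double* dst = out + (((R_xlen_t)n * W + sw) * H + sh) * C;
            const double* src = pc + (R_xlen_t)k * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dx;
}
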