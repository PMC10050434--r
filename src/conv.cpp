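// Hot loops of the 1-D convolution path. The unfold/fold pair moves data
// between the (n x L x C) sample layout and the (n*Lo x K*C) im2col matrix
// whose BLAS product with the weight matrix evaluates all convolution
// windows at once; both directions copy contiguous n-length blocks.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int n, int L, int C, int K) {
  int Lo = L - K + 1;
  NumericMatrix out(n * Lo, K * C);
  const double *x = X.begin();
  double *o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double *col = o + (size_t)(c * K + k) * n * Lo;
      const double *src = x + (size_t)c * n * L + (size_t)k * n;
      std::memcpy(col, src, sizeof(double) * (size_t)n * Lo);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_add_cpp(NumericMatrix M, int n, int L, int C, int K) {
  int Lo = L - K + 1;
  NumericVector out((size_t)n * L * C);
  double *o = out.begin();
  const double *m = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double *col = m + (size_t)(c * K + k) * n * Lo;
      double *dst = o + (size_t)c * n * L + (size_t)k * n;
      size_t len = (size_t)n * Lo;
      for (size_t i = 0; i < len; ++i) dst[i] += col[i];
    }
  }
  out.attr("dim") = IntegerVector::create(n, L, C);
  return out;
}

// Adds a per-column bias and applies ReLU in one pass (in place).
// [[Rcpp::export]]
void addbias_relu_inplace(NumericMatrix Z, NumericVector b, bool relu) {
  int nr = Z.nrow(), nc = Z.ncol();
  double *z = Z.begin();
  for (int f = 0; f < nc; ++f) {
    double bf = b[f];
    double *col = z + (size_t)f * nr;
    if (relu) {
      for (int i = 0; i < nr; ++i) {
        double v = col[i] + bf;
        col[i] = v > 0 ? v : 0;
      }
    } else {
      for (int i = 0; i < nr; ++i) col[i] += bf;
    }
  }
}
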