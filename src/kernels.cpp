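// Hot loops of the image encoder: im2col / col2im for the batched valid
// cross-correlation, and 2x2 max pooling with argmax tracking. Arrays use
// the (H, W, B, C) layout described in R/image-encoder.R; matrix products
// stay in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, IntegerVector dims, int M, int N) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = H - M + 1, Wo = W - N + 1;
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * B;
  NumericMatrix cols(rows, M * N * C);
  const double* x = X.begin();
  double* out = cols.begin();
  R_xlen_t col = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < M; ++i, ++col) {
        double* dst = out + col * rows;
        for (int b = 0; b < B; ++b) {
          const double* src = x + ((R_xlen_t)c * B + b) * H * W;
          for (int w = 0; w < Wo; ++w) {
            const double* s = src + (R_xlen_t)(w + j) * H + i;
            std::copy(s, s + Ho, dst);
            dst += Ho;
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcols, IntegerVector dims, int M, int N) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = H - M + 1, Wo = W - N + 1;
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * B;
  NumericVector dX((R_xlen_t)H * W * B * C);
  dX.attr("dim") = dims;
  double* x = dX.begin();
  const double* dc = dcols.begin();
  R_xlen_t col = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < M; ++i, ++col) {
        const double* src = dc + col * rows;
        for (int b = 0; b < B; ++b) {
          double* dst0 = x + ((R_xlen_t)c * B + b) * H * W;
          for (int w = 0; w < Wo; ++w) {
            double* d = dst0 + (R_xlen_t)(w + j) * H + i;
            const double* s = src + ((R_xlen_t)b * Wo + w) * Ho;
            for (int h = 0; h < Ho; ++h) d[h] += s[h];
          }
        }
      }
  return dX;
}

// 2x2/stride-2 max pooling; ties go to the first window cell in the fixed
// scan order (top-left, bottom-left, top-right, bottom-right).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector X, IntegerVector dims) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * B * C);
  IntegerVector which((R_xlen_t)Ho * Wo * B * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  const double* x = X.begin();
  double* o = out.begin();
  int* wh = which.begin();
  R_xlen_t k = 0;
  for (R_xlen_t bc = 0; bc < (R_xlen_t)B * C; ++bc) {
    const double* plane = x + bc * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h, ++k) {
        const double v0 = plane[(R_xlen_t)(2 * w) * H + 2 * h];
        const double v1 = plane[(R_xlen_t)(2 * w) * H + 2 * h + 1];
        const double v2 = plane[(R_xlen_t)(2 * w + 1) * H + 2 * h];
        const double v3 = plane[(R_xlen_t)(2 * w + 1) * H + 2 * h + 1];
        double best = v0; int bi = 0;
        if (v1 > best) { best = v1; bi = 1; }
        if (v2 > best) { best = v2; bi = 2; }
        if (v3 > best) { best = v3; bi = 3; }
        o[k] = best; wh[k] = bi;
      }
  }
  // output index k runs (h, w) within a (b, c) plane but the R array is
  // (Ho, Wo, B, C); both orders are h fastest then w then b*c, so they match
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dOut, IntegerVector which,
                              IntegerVector in_dims) {
  const int H = in_dims[0], W = in_dims[1], B = in_dims[2], C = in_dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dX((R_xlen_t)H * W * B * C);
  dX.attr("dim") = in_dims;
  double* x = dX.begin();
  const double* d = dOut.begin();
  const int* wh = which.begin();
  R_xlen_t k = 0;
  for (R_xlen_t bc = 0; bc < (R_xlen_t)B * C; ++bc) {
    double* plane = x + bc * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h, ++k) {
        const int bi = wh[k];
        const int dw = bi / 2, dh = bi % 2;
        plane[(R_xlen_t)(2 * w + dw) * H + 2 * h + dh] += d[k];
      }
  }
  return dX;
}
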