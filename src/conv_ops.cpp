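#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays with dim (H, W, C), column-major.
// im2col lays patches out so that a column for output position (ho, wo)
// holds values ordered (kh fastest, then kw, then c) -- matching the
// column-major flattening of a weight array with dim (k, k, C, Cout).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo);
  const double *xp = x.begin();
  double *op = out.begin();
  const int col_len = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      double *dst = op + (R_xlen_t)col * col_len;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *xc = xp + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          const bool win = (w >= 0 && w < W);
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            double v = 0.0;
            if (win && h >= 0 && h < H) v = xc[(R_xlen_t)w * H + h];
            dst[c * k * k + kw * k + kh] = v;
          }
        }
      }
    }
  }
  return out;
}

// Scatter-accumulate the adjoint of im2col: cols has dim (k*k*C, Ho*Wo).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const int col_len = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const double *src = cp + (R_xlen_t)col * col_len;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *xc = xp + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            xc[(R_xlen_t)w * H + h] += src[c * k * k + kw * k + kh];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Max pooling with zero padding ignored in the max (uses -Inf outside).
// [[Rcpp::export]]
NumericVector maxpool_cpp(NumericVector x, int H, int W, int C,
                          int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  const double *xp = x.begin();
  double *op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (R_xlen_t)c * H * W;
    double *oc = op + (R_xlen_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double m = R_NegInf;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            const double v = xc[(R_xlen_t)w * H + h];
            if (v > m) m = v;
          }
        }
        oc[(R_xlen_t)wo * Ho + ho] = m;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}
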