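#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Patch-lowering kernels for the convolution layers. Tensors arrive as
// dense numeric arrays laid out (height, width, batch, channel), column
// major; the patch matrix is (ho*wo*n) x (k*k*ch), rows ordered
// (h, w, n), columns shift-major with channels within each shift --
// matching the weight-matrix layout used on the R side. Padding bounds
// are hoisted out of the inner loops so the interior is a straight copy.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int h, int w, int n, int ch,
                         int k, int pad) {
  const int ho = h + 2 * pad - k + 1;
  const int wo = w + 2 * pad - k + 1;
  const R_xlen_t plane = (R_xlen_t)h * w;
  const R_xlen_t vol = plane * n;
  NumericMatrix m((R_xlen_t)ho * wo * n, (R_xlen_t)k * k * ch);
  const double *px = x.begin();
  double *pm = m.begin();
  R_xlen_t col = 0;
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy) {
      // valid source-row range for this vertical shift
      const int i_lo = std::max(0, pad - dy);
      const int i_hi = std::min(ho, h + pad - dy);   // exclusive
      const int len = i_hi - i_lo;
      for (int c = 0; c < ch; ++c, ++col) {
        double *out = pm + col * (R_xlen_t)ho * wo * n;
        for (int nn = 0; nn < n; ++nn) {
          const double *src = px + c * vol + nn * plane;
          for (int j = 0; j < wo; ++j, out += ho) {
            const int sc = j + dx - pad;
            if (sc < 0 || sc >= w) {
              std::memset(out, 0, sizeof(double) * ho);
              continue;
            }
            const double *colp = src + (R_xlen_t)sc * h + (i_lo + dy - pad);
            if (len < ho) std::memset(out, 0, sizeof(double) * ho);
            if (len > 0) std::memcpy(out + i_lo, colp, sizeof(double) * len);
          }
        }
      }
    }
  }
  return m;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dm, int h, int w, int n, int ch,
                         int k, int pad) {
  const int ho = h + 2 * pad - k + 1;
  const int wo = w + 2 * pad - k + 1;
  const R_xlen_t plane = (R_xlen_t)h * w;
  const R_xlen_t vol = plane * n;
  NumericVector dx_out((R_xlen_t)h * w * n * ch);
  const double *pdm = dm.begin();
  double *pdx = dx_out.begin();
  R_xlen_t col = 0;
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy) {
      const int i_lo = std::max(0, pad - dy);
      const int i_hi = std::min(ho, h + pad - dy);
      for (int c = 0; c < ch; ++c, ++col) {
        const double *in = pdm + col * (R_xlen_t)ho * wo * n;
        for (int nn = 0; nn < n; ++nn) {
          double *dst = pdx + c * vol + nn * plane;
          for (int j = 0; j < wo; ++j, in += ho) {
            const int sc = j + dx - pad;
            if (sc < 0 || sc >= w) continue;
            double *colp = dst + (R_xlen_t)sc * h + (dy - pad);
            for (int i = i_lo; i < i_hi; ++i) colp[i] += in[i];
          }
        }
      }
    }
  }
  dx_out.attr("dim") = IntegerVector::create(h, w, n, ch);
  return dx_out;
}
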