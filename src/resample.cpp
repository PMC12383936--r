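#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear gather: sample img at fractional 0-based (row, col) positions,
// constant `fill` outside the matrix, clamped at the last row/column.
// [[Rcpp::export(name = ".bilinear_core")]]
NumericVector bilinear_core(const NumericMatrix& img,
                            const NumericVector& rows,
                            const NumericVector& cols,
                            double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = rows.size();
  NumericVector out(n, fill);
  const double eps = 1e-9;   // round-trip polar maps land eps outside
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = rows[i], c = cols[i];
    if (!(r >= -eps && c >= -eps && r <= nr - 1.0 + eps && c <= nc - 1.0 + eps))
      continue;
    if (r < 0.0) r = 0.0;
    if (c < 0.0) c = 0.0;
    if (r > nr - 1.0) r = nr - 1.0;
    if (c > nc - 1.0) c = nc - 1.0;
    const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    const double fr = r - r0, fc = c - c0;
    const int r1 = r0 + 1 > nr - 1 ? nr - 1 : r0 + 1;
    const int c1 = c0 + 1 > nc - 1 ? nc - 1 : c0 + 1;
    out[i] = img(r0, c0) * (1 - fr) * (1 - fc) +
             img(r1, c0) * fr * (1 - fc) +
             img(r0, c1) * (1 - fr) * fc +
             img(r1, c1) * fr * fc;
  }
  return out;
}
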