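#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Running min/max with a flat structuring element, applied down each column
// (columns are spectra, rows are m/z channels). Window half-width h channels;
// boundaries use the partial window, so the opening of a constant spectrum is
// that constant.
// [[Rcpp::export(name = ".morph_cols")]]
NumericMatrix morph_cols(const NumericMatrix& x, const int h, const bool take_min) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(0, i - h);
      const int hi = std::min(n - 1, i + h);
      double v = col[lo];
      if (take_min) {
        for (int k = lo + 1; k <= hi; ++k) v = std::min(v, col[k]);
      } else {
        for (int k = lo + 1; k <= hi; ++k) v = std::max(v, col[k]);
      }
      o[i] = v;
    }
  }
  return out;
}
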