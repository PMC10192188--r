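#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy: ordered pairs of distinct
// length-m (B) and length-(m+1) (A) templates within Chebyshev
// distance r, templates indexed 1..n-m for both lengths.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  double a = 0.0, b = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dm) dm = d;
      }
      if (dm <= r) {
        b += 1.0;
        double d1 = std::fabs(x[i + m] - x[j + m]);
        if (d1 <= r && dm <= r) a += 1.0;
      }
    }
  }
  // ordered pairs are twice the unordered count
  return NumericVector::create(2.0 * a, 2.0 * b);
}
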