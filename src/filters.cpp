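#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y = filter(b, a, x).
// Coefficients are normalised so a[0] == 1 on entry.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int m = std::max(nb, na) - 1;
  std::vector<double> z(m, 0.0), bb(m + 1, 0.0), aa(m + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (m > 0)
      z[m - 1] = bb[m] * xi - aa[m] * yi;
    y[i] = yi;
  }
  return y;
}
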