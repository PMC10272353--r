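#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 (normalised by caller).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
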