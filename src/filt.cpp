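#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 after normalisation.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> z(nz, 0.0);
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
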