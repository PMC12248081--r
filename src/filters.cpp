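#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 (caller normalizes).
// Used twice (forward, then reversed) by filtfilt_one() for zero-phase output.
// [[Rcpp::export(name = ".iir_df2t")]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x,
                       NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (zi.size() == (R_xlen_t)nz)
    for (int i = 0; i < nz; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + z[0];
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}
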