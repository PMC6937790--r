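#include <Rcpp.h>
using namespace Rcpp;

// Cross-correlation of the signal with a bank of scale-dependent wavelet
// kernels under zero extension outside the signal support.  The kernel for
// scale s holds (1/sqrt(s)) * psi(m/s) * dt at integer offsets m >= 0, so
// row si of the result is  coef[si, tau] = sum_m x[tau + m] * k[m].
// [[Rcpp::export]]
NumericMatrix cwt_correlate(NumericVector x, List kernels) {
  const int n = x.size();
  const int S = kernels.size();
  NumericMatrix out(S, n);
  for (int si = 0; si < S; ++si) {
    NumericVector k = kernels[si];
    const int L = k.size();
    const double *kp = k.begin();
    const double *xp = x.begin();
    for (int tau = 0; tau < n; ++tau) {
      double acc = 0.0;
      const int mmax = std::min(L, n - tau);
      for (int m = 0; m < mmax; ++m) acc += xp[tau + m] * kp[m];
      out(si, tau) = acc;
    }
  }
  return out;
}
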