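#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be non-zero.
static std::vector<double> iir_filter(const std::vector<double>& b,
                                      const std::vector<double>& a,
                                      const std::vector<double>& x) {
  const size_t n = x.size();
  const size_t nb = b.size(), na = a.size();
  const size_t nk = std::max(nb, na);
  std::vector<double> bb(nk, 0.0), aa(nk, 0.0);
  for (size_t i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (size_t i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(nk, 0.0), y(n);
  double* zp = z.data();
  const double* bp = bb.data();
  const double* ap = aa.data();
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bp[0] * xi + zp[0];
    for (size_t j = 1; j < nk; ++j)
      zp[j - 1] = bp[j] * xi + zp[j] - ap[j] * yi;
    y[i] = yi;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_iir_filter")]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end()),
      xv(x.begin(), x.end());
  std::vector<double> y = iir_filter(bv, av, xv);
  return NumericVector(y.begin(), y.end());
}

// Zero-phase forward-backward IIR filtering with odd (reflected) edge padding,
// as in the usual filtfilt formulation.
// [[Rcpp::export(name = ".cpp_filtfilt")]]
NumericVector cpp_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size();
  const int nf = std::max(b.size(), a.size());
  const int pad = std::min(3 * (nf - 1) > 0 ? 3 * (nf - 1) : 1, n - 1);
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  std::vector<double> xe(n + 2 * pad);
  for (int i = 0; i < pad; ++i) xe[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xe[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xe[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  std::vector<double> y = iir_filter(bv, av, xe);
  std::reverse(y.begin(), y.end());
  y = iir_filter(bv, av, y);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[pad + i];
  return out;
}

// Linear-phase FIR filtering with group-delay compensation: the output sample i
// is sum_k h[k] * x[i + (L-1)/2 - k] (zero padded at the edges), so a
// symmetric kernel introduces no shift. L must be odd.
// [[Rcpp::export(name = ".cpp_fir_centered")]]
NumericVector cpp_fir_centered(NumericVector h, NumericVector x) {
  const int L = h.size(), n = x.size();
  const int half = (L - 1) / 2;
  NumericVector out(n);
  const double* hp = REAL(h);
  const double* xp = REAL(x);
  double* op = REAL(out);
  // bulk: no boundary clipping needed for i in [half, n - L + half)
  const int lo = std::min(half, n), hi = std::max(lo, n - (L - 1 - half));
  for (int i = 0; i < lo; ++i) {
    double acc = 0.0;
    const int kmax = std::min(L - 1, i + half);
    for (int k = i + half - std::min(i + half, n - 1); k <= kmax; ++k)
      acc += hp[k] * xp[i + half - k];
    op[i] = acc;
  }
  for (int i = lo; i < hi; ++i) {
    const double* xs = xp + i + half;
    double acc = 0.0;
    for (int k = 0; k < L; ++k) acc += hp[k] * xs[-k];
    op[i] = acc;
  }
  for (int i = hi; i < n; ++i) {
    double acc = 0.0;
    const int kmin = std::max(0, i + half - (n - 1));
    const int kmax = std::min(L - 1, i + half);
    for (int k = kmin; k <= kmax; ++k) acc += hp[k] * xp[i + half - k];
    op[i] = acc;
  }
  return out;
}

// Add amp[j] * kernel at sample offset idx[j] (1-based) into x, truncating at
// the end of the series. Used to superpose event-locked responses.
// [[Rcpp::export(name = ".cpp_add_events")]]
NumericVector cpp_add_events(NumericVector x, IntegerVector idx,
                             NumericVector amp, NumericVector kernel) {
  NumericVector out = clone(x);
  const int n = out.size(), L = kernel.size();
  for (int j = 0; j < idx.size(); ++j) {
    const int start = idx[j] - 1;
    if (start < 0 || start >= n) continue;
    const int len = std::min(L, n - start);
    const double a = amp[j];
    if (a == 0.0) continue;
    for (int k = 0; k < len; ++k) out[start + k] += a * kernel[k];
  }
  return out;
}
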