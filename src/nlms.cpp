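#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Normalized LMS adaptive noise cancellation. The filter predicts the
// component of `primary` linearly related to the last `L` reference samples
// and outputs the prediction error (the cleaned signal).
// [[Rcpp::export]]
NumericVector nlms_cancel(NumericVector primary, NumericVector reference,
                          double mu, int L) {
  const int n = primary.size();
  const double eps = 1e-8;
  NumericVector out(n);
  std::vector<double> w(L, 0.0), x(L, 0.0);
  double norm = 0.0;
  int head = 0; // circular buffer index of the newest sample
  for (int i = 0; i < n; ++i) {
    head = head == 0 ? L - 1 : head - 1;
    norm += reference[i] * reference[i] - x[head] * x[head];
    if (norm < 0) norm = 0; // guard against rounding drift
    x[head] = reference[i];
    double y = 0.0;
    int idx = head;
    for (int t = 0; t < L; ++t) {
      y += w[t] * x[idx];
      if (++idx == L) idx = 0;
    }
    const double e = primary[i] - y;
    const double g = mu * e / (eps + norm);
    idx = head;
    for (int t = 0; t < L; ++t) {
      w[t] += g * x[idx];
      if (++idx == L) idx = 0;
    }
    out[i] = e;
  }
  return out;
}

// Forward-backward IIR filtering (zero net phase), the classic filtfilt
// scheme: odd reflection padding of 3 * (filter order) samples at both ends,
// one forward and one reverse pass of the direct-form-II-transposed filter,
// padding discarded.
static void df2t_pass(const std::vector<double>& b, const std::vector<double>& a,
                      std::vector<double>& x) {
  const int nf = b.size();
  std::vector<double> z(nf, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int t = 1; t < nf; ++t)
      z[t - 1] = b[t] * xi + z[t] - a[t] * yi;
    x[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector iir_filtfilt(NumericVector b, NumericVector a, NumericVector x) {
  const int nf = std::max(b.size(), a.size());
  const int pad = 3 * (nf - 1);
  const int n = x.size();
  if (n <= pad) stop("signal too short for filtfilt padding");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  bb.resize(nf, 0.0);
  aa.resize(nf, 0.0);
  std::vector<double> y(n + 2 * pad);
  for (int i = 0; i < pad; ++i) y[i] = 2 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) y[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) y[pad + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  df2t_pass(bb, aa, y);
  std::reverse(y.begin(), y.end());
  df2t_pass(bb, aa, y);
  std::reverse(y.begin(), y.end());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = y[pad + i];
  return out;
}
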