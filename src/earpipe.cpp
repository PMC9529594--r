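#include <Rcpp.h>
using namespace Rcpp;

// Normalized least-mean-squares adaptive filter.
//
// estimate(n) = w(n)' r(n..n-taps+1), cleaned = primary - estimate,
// w(n+1) = w(n) + mu * e(n) * r / (||r||^2 + eps).
// The first n_taps samples are passed through untouched (estimate forced to 0)
// because the regressor window is undefined there. reset_every <= 0 disables
// rolling-window weight resets.
// [[Rcpp::export(name = ".nlms_core")]]
List nlms_core(NumericVector primary, NumericVector reference,
               int n_taps, double mu, double eps, int reset_every) {
  int n = primary.size();
  NumericVector est(n), cleaned(n);
  std::vector<double> w(n_taps, 0.0);
  for (int i = 0; i < n; ++i) {
    if (reset_every > 0 && i > 0 && (i % reset_every) == 0)
      std::fill(w.begin(), w.end(), 0.0);
    if (i < n_taps) {
      est[i] = 0.0;
      cleaned[i] = primary[i];
      continue;
    }
    // regressor r = reference[i], reference[i-1], ..., reference[i-n_taps+1]
    double yhat = 0.0, norm = 0.0;
    for (int k = 0; k < n_taps; ++k) {
      double rk = reference[i - k];
      yhat += w[k] * rk;
      norm += rk * rk;
    }
    est[i] = yhat;
    double e = primary[i] - yhat;
    cleaned[i] = e;
    double g = mu * e / (norm + eps);
    for (int k = 0; k < n_taps; ++k)
      w[k] += g * reference[i - k];
  }
  return List::create(_["cleaned"] = cleaned, _["estimate"] = est);
}

// Higuchi curve lengths L(k), k = 1..k_max, averaged over offsets m = 1..k:
// L_m(k) = ((n-1) / (floor((n-m)/k) * k^2)) * sum_i |x(m+ik) - x(m+(i-1)k)|.
// The fractal dimension is the slope of ln L(k) on ln(1/k), fitted in R.
// [[Rcpp::export(name = ".higuchi_lengths")]]
NumericVector higuchi_lengths(NumericVector x, int k_max) {
  int n = x.size();
  NumericVector L(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    int used = 0;
    for (int m = 0; m < k; ++m) { // 0-based offset, m+1 in the 1-based formula
      int nm = (n - 1 - m) / k;   // number of increments
      if (nm < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nm; ++i)
        s += std::abs(x[m + i * k] - x[m + (i - 1) * k]);
      acc += s * (double)(n - 1) / ((double)nm * (double)k * (double)k);
      ++used;
    }
    L[k - 1] = used > 0 ? acc / used : NA_REAL;
  }
  return L;
}
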