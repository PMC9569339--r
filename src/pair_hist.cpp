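#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Histogram of log(kappa_i * kappa_j) over unordered pairs, used to evaluate
// the ensemble mean degree for many mu values without materializing the
// O(N^2) product matrix.
// [[Rcpp::export]]
List pair_log_hist_cpp(NumericVector log_kappa, int n_bins) {
  const int N = log_kappa.size();
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double s = log_kappa[i] + log_kappa[j];
      if (s < lo) lo = s;
      if (s > hi) hi = s;
    }
  }
  if (!(hi > lo)) {
    return List::create(_["centers"] = NumericVector::create(lo),
                        _["weights"] = NumericVector::create(
                            0.5 * (double)N * (N - 1)));
  }
  NumericVector counts(n_bins);
  const double width = (hi - lo) / n_bins;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double s = log_kappa[i] + log_kappa[j];
      int b = (int)((s - lo) / width);
      if (b >= n_bins) b = n_bins - 1;
      counts[b] += 1.0;
    }
  }
  std::vector<double> centers, weights;
  for (int b = 0; b < n_bins; ++b) {
    if (counts[b] > 0) {
      centers.push_back(lo + (b + 0.5) * width);
      weights.push_back(counts[b]);
    }
  }
  return List::create(_["centers"] = wrap(centers),
                      _["weights"] = wrap(weights));
}
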