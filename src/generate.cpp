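#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Bernoulli edge draws under the S^D gravity law. One uniform is
// consumed per unordered pair in (i, j) lexicographic order so that the edge
// set is reproducible bit-for-bit from R's RNG state. Node indices in the
// returned matrix are 0-based.
// [[Rcpp::export]]
IntegerMatrix generate_edges_cpp(NumericMatrix pos, NumericVector kappa,
                                 double R, double mu, double beta,
                                 int D, bool beta_inf) {
  const int N = pos.nrow();
  const int dim = pos.ncol();
  std::vector<int> from, to;
  from.reserve(8 * N);
  to.reserve(8 * N);
  const double invD = 1.0 / D;
  for (int i = 0; i < N - 1; ++i) {
    const double mki = mu * kappa[i];
    for (int j = i + 1; j < N; ++j) {
      double dot = 0.0;
      for (int d = 0; d < dim; ++d) dot += pos(i, d) * pos(j, d);
      if (dot > 1.0) dot = 1.0;
      if (dot < -1.0) dot = -1.0;
      const double dtheta = std::acos(dot);
      const double chi = R * dtheta / std::pow(mki * kappa[j], invD);
      double p;
      if (beta_inf) {
        p = chi < 1.0 ? 1.0 : (chi > 1.0 ? 0.0 : 0.5);
      } else {
        p = 1.0 / (1.0 + std::pow(chi, beta));
      }
      const double u = R::unif_rand();
      if (u < p) {
        from.push_back(i);
        to.push_back(j);
      }
    }
  }
  const int m = from.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}
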