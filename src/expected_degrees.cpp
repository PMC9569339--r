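#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// I(t) = \int_0^pi sin^(D-1)(theta) / (1 + (theta/t)^beta) dtheta,
// Gauss-Legendre on [0, min(t, pi)] and [min(t, pi), pi] (the integrand is
// smooth away from the Fermi transition at theta = t). beta < 0 encodes the
// zero-temperature limit, where the integral is the incomplete integral of
// sin^(D-1) with closed form through the regularized incomplete beta.
static double fermi_integral(double t, int D, double beta,
                             const std::vector<double>& x,
                             const std::vector<double>& w) {
  const double PI = M_PI;
  if (beta < 0) {  // step law
    double s = t < PI ? t : PI;
    double a = 0.5 * D, b = 0.5;
    double full = std::exp(R::lbeta(a, b));
    if (s <= 0.5 * PI) {
      double u = std::sin(s);
      return 0.5 * full * R::pbeta(u * u, a, b, 1, 0);
    }
    double u = std::sin(PI - s);
    return full - 0.5 * full * R::pbeta(u * u, a, b, 1, 0);
  }
  const int n = x.size();
  double s = t < PI ? t : PI;
  double total = 0.0;
  // segment [0, s]
  double hw = 0.5 * s, mid = 0.5 * s;
  for (int q = 0; q < n; ++q) {
    double theta = hw * x[q] + mid;
    double f = std::pow(std::sin(theta), D - 1) /
               (1.0 + std::pow(theta / t, beta));
    total += hw * w[q] * f;
  }
  if (s < PI) {
    hw = 0.5 * (PI - s);
    mid = 0.5 * (PI + s);
    for (int q = 0; q < n; ++q) {
      double theta = hw * x[q] + mid;
      double f = std::pow(std::sin(theta), D - 1) /
                 (1.0 + std::pow(theta / t, beta));
      total += hw * w[q] * f;
    }
  }
  return total;
}

// Expected degree of every degree class against the class population
// (multiplicities `mult`, each class excluding its own node), for the S^D
// model with the given mu, R. `beta < 0` means beta = Inf.
// [[Rcpp::export]]
NumericVector expected_degrees_cpp(NumericVector kappa, IntegerVector mult,
                                   int D, double beta, double mu, double R,
                                   double prefactor,
                                   NumericVector gl_nodes,
                                   NumericVector gl_weights) {
  const int C = kappa.size();
  std::vector<double> x(gl_nodes.begin(), gl_nodes.end());
  std::vector<double> w(gl_weights.begin(), gl_weights.end());
  const double invD = 1.0 / D;
  NumericVector kbar(C);
  for (int i = 0; i < C; ++i) {
    for (int j = i; j < C; ++j) {
      double t = std::pow(mu * kappa[i] * kappa[j], invD) / R;
      double I = fermi_integral(t, D, beta, x, w);
      double wij = mult[j] - (i == j ? 1 : 0);
      kbar[i] += wij * I;
      if (j > i) kbar[j] += (mult[i] - 0) * I;
    }
  }
  for (int i = 0; i < C; ++i) kbar[i] *= prefactor;
  return kbar;
}
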