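// Exact Polya-Gamma PG(1, psi) sampler (Devroye-type alternating-series
// rejection with truncation point 0.64), driving R's RNG so that set.seed()
// controls every draw.
#include <Rcpp.h>

static const double TRUNC = 0.64;

// Piecewise coefficients a_n(x) of the Jacobi-theta density series.
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-0.5 * np * np * M_PI * M_PI * x);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// CDF at t of the inverse-Gaussian(mu = 1/z, lambda = 1) distribution,
// written to stay finite for large z.
static double pigauss(double t, double z) {
  double rt = std::sqrt(t);
  double a = R::pnorm((t * z - 1.0) / rt, 0.0, 1.0, 1, 0);
  double b = std::exp(2.0 * z + R::pnorm(-(t * z + 1.0) / rt, 0.0, 1.0, 1, 1));
  return a + b;
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double x;
  if (z < 1.0 / TRUNC) {
    // mu > t: rejection from a truncated chi-like proposal; exact as z -> 0
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  for (;;) {
    double y = R::norm_rand();
    y = y * y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= TRUNC) return x;
  }
}

// One PG(1, psi) draw.  PG(1, psi) = J*(1, psi/2) / 4.
double rpg1(double psi) {
  double z = 0.5 * std::fabs(psi);
  double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  double ratio = p / (p + q);
  for (;;) {
    double x;
    if (R::unif_rand() < ratio)
      x = TRUNC + R::exp_rand() / K;  // exponential right tail
    else
      x = rtigauss(z);
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, psi) variates
//'
//' One exact draw per element of `psi`. Used internally by the Gibbs
//' samplers; exported for diagnostic checks (e.g. the identity
//' E\[PG(1, z)\] = tanh(z/2) / (2 z)).
//'
//' @param psi numeric vector of tilting parameters.
//' @return numeric vector of PG(1, psi_i) draws.
//' @export
// [[Rcpp::export]]
Rcpp::NumericVector rpg(Rcpp::NumericVector psi) {
  int n = psi.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(psi[i]);
  return out;
}
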