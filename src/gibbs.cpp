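// Polya-Gamma Gibbs samplers for the Bayesian logistic presence-absence
// models.  The augmented model gives conjugate Gaussian full conditionals
// for beta and for the site-level spatial effects eta, a conjugate
// inverse-gamma update for sigma2 | eta, phi, and a random-walk Metropolis
// step on the logit-transformed range parameter r = 1/phi within its
// uniform prior bounds.  All randomness comes from R's RNG.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

double rpg1(double psi);  // rpg.cpp

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// x ~ N(Prec^{-1} b, Prec^{-1}) given upper Cholesky U with U'U = Prec.
static arma::vec sample_gaussian_canonical(const arma::mat& U,
                                           const arma::vec& b) {
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(b.n_elem));
}

// Correlation matrix exp(-phi * dist) with relative diagonal jitter.
static arma::mat corr_mat(const arma::mat& dist, double phi, double jitter) {
  arma::mat R = arma::exp(-phi * dist);
  R.diag() += jitter;
  return R;
}

// [[Rcpp::export]]
Rcpp::List gibbs_logistic(const arma::vec& y, const arma::mat& X,
                          const arma::uvec& site, const arma::mat& dist,
                          bool spatial, double beta_var, double r_lower,
                          double r_upper, double s2_shape, double s2_scale,
                          int n_retain, int burn, int thin, double jitter,
                          double prop_sd, bool sample_cov, double sigma2_init,
                          double phi_init) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int S = spatial ? dist.n_rows : 0;

  arma::vec beta(p, arma::fill::zeros);
  arma::vec eta(std::max(S, 1), arma::fill::zeros);
  if (!spatial) eta.zeros();
  double sigma2 = sigma2_init;
  double r = 1.0 / phi_init;  // range-scale parameter, Unif(r_lower, r_upper)
  double theta = std::log((r - r_lower) / (r_upper - r));

  arma::mat Binv = arma::eye(p, p) / beta_var;

  // current correlation factorisation (spatial only)
  arma::mat Rchol, Rinv;
  double logdetR = 0.0;
  if (spatial) {
    arma::mat R = corr_mat(dist, 1.0 / r, jitter);
    Rchol = arma::chol(R);
    logdetR = 2.0 * arma::sum(arma::log(Rchol.diag()));
    Rinv = arma::inv_sympd(R);
  }

  arma::mat beta_out(n_retain, p);
  arma::mat eta_out(spatial ? n_retain : 0, S);
  arma::vec sigma2_out(spatial ? n_retain : 0);
  arma::vec phi_out(spatial ? n_retain : 0);

  int phi_acc = 0, phi_try = 0, win_acc = 0, win_try = 0;
  const int total = burn + n_retain * thin;
  int stored = 0;

  for (int it = 0; it < total; ++it) {
    // --- Polya-Gamma augmentation
    arma::vec psi = X * beta;
    if (spatial)
      for (int i = 0; i < n; ++i) psi(i) += eta(site(i));
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega(i) = rpg1(psi(i));
    arma::vec kappa = y - 0.5;

    // --- beta | omega, eta
    arma::vec resid = kappa;
    if (spatial)
      for (int i = 0; i < n; ++i) resid(i) -= omega(i) * eta(site(i));
    arma::mat Xw = X.each_col() % omega;
    arma::mat Vinv = X.t() * Xw + Binv;
    arma::mat U = arma::chol(Vinv);
    beta = sample_gaussian_canonical(U, X.t() * resid);

    if (spatial) {
      // --- eta | omega, beta, sigma2, phi
      arma::vec xb = X * beta;
      arma::vec d(S, arma::fill::zeros), m(S, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        d(site(i)) += omega(i);
        m(site(i)) += kappa(i) - omega(i) * xb(i);
      }
      arma::mat P = Rinv / sigma2;
      P.diag() += d;
      arma::mat Up = arma::chol(P);
      eta = sample_gaussian_canonical(Up, m);

      double qf = arma::as_scalar(eta.t() * Rinv * eta);

      if (sample_cov) {
        // --- sigma2 | eta, phi  ~ InvGamma(shape + S/2, scale + qf/2)
        double shape = s2_shape + 0.5 * S;
        double scale = s2_scale + 0.5 * qf;
        sigma2 = scale / R::rgamma(shape, 1.0);

        // --- r = 1/phi via RW Metropolis on theta = logit scale
        double theta_prop = theta + prop_sd * R::norm_rand();
        double r_prop = r_lower + (r_upper - r_lower) /
                                      (1.0 + std::exp(-theta_prop));
        arma::mat Rp = corr_mat(dist, 1.0 / r_prop, jitter);
        arma::mat Ucp;
        bool ok = arma::chol(Ucp, Rp);
        ++phi_try;
        ++win_try;
        if (ok) {
          double logdet_p = 2.0 * arma::sum(arma::log(Ucp.diag()));
          arma::vec v = arma::solve(arma::trimatl(Ucp.t()), eta);
          double qf_p = arma::dot(v, v);
          // uniform prior on r; Jacobian of the logit transform
          double lj_cur = std::log(r - r_lower) + std::log(r_upper - r);
          double lj_prop =
              std::log(r_prop - r_lower) + std::log(r_upper - r_prop);
          double lr = -0.5 * (logdet_p - logdetR) -
                      0.5 * (qf_p - qf) / sigma2 + (lj_prop - lj_cur);
          if (std::log(R::unif_rand()) < lr) {
            r = r_prop;
            theta = theta_prop;
            Rchol = Ucp;
            logdetR = logdet_p;
            Rinv = arma::inv_sympd(Rp);
            ++phi_acc;
            ++win_acc;
          }
        }
        // adapt the proposal scale toward 20-50% acceptance during burn-in
        if (it < burn && win_try == 50) {
          double rate = win_acc / 50.0;
          if (rate > 0.5)
            prop_sd *= 1.25;
          else if (rate < 0.2)
            prop_sd /= 1.25;
          win_acc = 0;
          win_try = 0;
        }
      }
    }

    if (it >= burn && (it - burn) % thin == 0 && stored < n_retain) {
      beta_out.row(stored) = beta.t();
      if (spatial) {
        eta_out.row(stored) = eta.t();
        sigma2_out(stored) = sigma2;
        phi_out(stored) = 1.0 / r;
      }
      ++stored;
    }
  }

  double acc_rate = phi_try > 0 ? (double)phi_acc / phi_try : NA_REAL;
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_out, Rcpp::Named("eta") = eta_out,
      Rcpp::Named("sigma2") = sigma2_out, Rcpp::Named("phi") = phi_out,
      Rcpp::Named("accept_phi") = acc_rate,
      Rcpp::Named("prop_sd") = prop_sd);
}
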