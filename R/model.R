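# Model definition and MCMC fitting.

#' Prior specification
#'
#' Independent normal priors on the regression coefficients, a uniform
#' prior on the range-scale parameter 1/phi (meters), and an
#' inverse-gamma prior on the GP variance sigma2.
#'
#' The coefficient prior is N(0, `beta_var`) with `beta_var` a
#' *variance*; the conventional weakly-informative choice written
#' "N(0, 2.5)" is ambiguous between variance and sd, so the sd reading is
#' available as `prior_spec(beta_var = 2.5^2)`. The inverse-gamma is
#' parameterized by shape and scale: density proportional to
#' `x^-(shape+1) exp(-scale/x)` (so InvGam(2, 2) has mean 2).
#'
#' @param beta_var prior variance of each coefficient.
#' @param inv_phi_lower,inv_phi_upper bounds (m) of the uniform prior on
#'   1/phi.
#' @param sigma2_shape,sigma2_scale inverse-gamma hyperparameters.
#' @return object of class `buv_priors`.
#' @export
prior_spec <- function(beta_var = 2.5, inv_phi_lower = 50,
                       inv_phi_upper = 1500, sigma2_shape = 2,
                       sigma2_scale = 2) {
  stopifnot(beta_var > 0, inv_phi_lower > 0,
            inv_phi_upper > inv_phi_lower, sigma2_shape > 0,
            sigma2_scale > 0)
  structure(list(beta_var = beta_var, inv_phi_lower = inv_phi_lower,
                 inv_phi_upper = inv_phi_upper,
                 sigma2_shape = sigma2_shape,
                 sigma2_scale = sigma2_scale), class = "buv_priors")
}

#' MCMC configuration
#'
#' Defaults follow common practice for these models: 5000 retained
#' samples after 1000 burn-in iterations, thinning every 2nd iterate for
#' the non-spatial model and every 10th for the spatial model (the
#' spatial chain mixes more slowly because sigma2 and phi are only
#' weakly identified from binary data).
#'
#' @param spatial fit the GP random effect?
#' @param n_retained retained posterior draws.
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in iterate; `NULL` picks
#'   2 (non-spatial) or 10 (spatial).
#' @param seed integer seed.
#' @param jitter relative diagonal nugget added to the GP correlation
#'   matrix before factorization.
#' @param prop_sd initial random-walk sd for the logit-transformed 1/phi
#'   step; adapted toward 20--50% acceptance during burn-in, then frozen.
#' @param sigma2_fixed optionally hold sigma2 (and phi) fixed at this
#'   value instead of sampling them; mainly for checking that the spatial
#'   model collapses to the non-spatial one as sigma2 -> 0.
#' @param sigma2_init,phi_init starting values (`NULL`: prior-guided).
#' @return object of class `buv_fit_config`.
#' @export
fit_config <- function(spatial = TRUE, n_retained = 5000, burn_in = 1000,
                       thin = NULL, seed = 1, jitter = 1e-8,
                       prop_sd = 0.8, sigma2_fixed = NULL,
                       sigma2_init = NULL, phi_init = NULL) {
  if (is.null(thin)) thin <- if (spatial) 10L else 2L
  stopifnot(n_retained >= 1, burn_in >= 1, thin >= 1, jitter >= 0,
            prop_sd > 0)
  structure(list(spatial = spatial, n_retained = as.integer(n_retained),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), jitter = jitter,
                 prop_sd = prop_sd, sigma2_fixed = sigma2_fixed,
                 sigma2_init = sigma2_init, phi_init = phi_init),
            class = "buv_fit_config")
}

#' Exponential spatial covariance matrix
#'
#' `sigma2 * exp(-phi * d_ij)` for Euclidean distances between site
#' coordinates (planar meters), with diagonal `sigma2 * (1 + jitter)`.
#'
#' @param sites two-column matrix or data.frame of easting/northing, or a
#'   `buv_survey` object.
#' @param sigma2 variance (partial sill).
#' @param phi decay parameter (1/m).
#' @param jitter relative diagonal nugget.
#' @return symmetric `n_sites` x `n_sites` covariance matrix.
#' @export
exp_covariance <- function(sites, sigma2, phi, jitter = 0) {
  if (inherits(sites, "buv_survey")) sites <- site_coords(sites)
  coords <- coord_matrix(sites)
  stopifnot(sigma2 > 0, phi > 0, jitter >= 0)
  C <- sigma2 * exp(-phi * unname(as.matrix(dist(coords))))
  diag(C) <- sigma2 * (1 + jitter)
  C
}

#' Effective spatial range
#'
#' The distance at which the exponential correlation drops to 0.05,
#' approximately `3 / phi`.
#'
#' @param phi decay parameter (1/m), or a vector of posterior draws.
#' @return range in meters.
#' @export
effective_range <- function(phi) {
  if (any(phi <= 0)) stop("phi must be positive")
  3 / phi
}

# Bernoulli log likelihood with probability clipping.
bernoulli_loglik <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Unnormalized log posterior density
#'
#' Bernoulli log-likelihood of the (spatial) logistic model plus the log
#' prior densities. Returns `-Inf` when 1/phi falls outside its uniform
#' bounds or `sigma2 <= 0`. Used for diagnostics and for validating the
#' sampler against brute-force integration; the Gibbs sampler itself
#' never evaluates it.
#'
#' @param beta coefficient vector (length = design-matrix columns).
#' @param eta per-site spatial effects (ignored when `spatial = FALSE`).
#' @param sigma2,phi GP parameters (ignored when `spatial = FALSE`).
#' @param data a `buv_survey` with standardized covariates and presence.
#' @param priors a [prior_spec()] object.
#' @param spatial include the GP term and its priors?
#' @return scalar log density (unnormalized).
#' @export
log_posterior <- function(beta, eta = NULL, sigma2 = NULL, phi = NULL,
                          data, priors = prior_spec(), spatial = FALSE) {
  X <- build_design_matrix(data)
  stopifnot(length(beta) == ncol(X))
  if (any(!is.finite(beta))) stop("non-finite beta")
  y <- data$observations$presence
  lp <- drop(X %*% beta)
  prior <- sum(stats::dnorm(beta, 0, sqrt(priors$beta_var), log = TRUE))
  if (spatial) {
    stopifnot(!is.null(eta), !is.null(sigma2), !is.null(phi))
    if (any(!is.finite(eta))) stop("non-finite eta")
    if (sigma2 <= 0) return(-Inf)
    r <- 1 / phi
    if (r < priors$inv_phi_lower || r > priors$inv_phi_upper) return(-Inf)
    lp <- lp + eta[data$obs_to_site]
    C <- exp_covariance(site_coords(data), sigma2, phi)
    L <- chol(C)
    v <- backsolve(L, eta, transpose = TRUE)
    prior <- prior - sum(log(diag(L))) - 0.5 * sum(v^2) -
      0.5 * length(eta) * log(2 * pi)
    # InvGamma(shape, scale) on sigma2; Unif on 1/phi (constant, dropped)
    prior <- prior - (priors$sigma2_shape + 1) * log(sigma2) -
      priors$sigma2_scale / sigma2
  }
  bernoulli_loglik(y, invlogit(lp)) + prior
}

#' Fit a (spatial) Bayesian logistic model by MCMC
#'
#' Standardizes depth and visibility, builds the 10-column design matrix
#' and runs the Polya-Gamma Gibbs sampler. For the spatial model the GP
#' random effect is defined at the unique site coordinates; sigma2 gets a
#' conjugate inverse-gamma update and 1/phi a random-walk Metropolis step
#' within its uniform prior bounds.
#'
#' @param data a `buv_survey` dataset with raw covariates and a 0/1
#'   presence column containing both classes.
#' @param priors a [prior_spec()] object.
#' @param config a [fit_config()] object.
#' @return object of class `buv_draws`: list with `beta` (draws x 10),
#'   and for spatial fits `eta` (draws x sites), `sigma2`, `phi`;
#'   plus `sites`, `std_params`, `priors`, `config`, `accept` (per-block
#'   acceptance rates) and `term_names`.
#' @export
fit_model <- function(data, priors = prior_spec(), config = fit_config()) {
  stopifnot(inherits(data, "buv_survey"), inherits(priors, "buv_priors"),
            inherits(config, "buv_fit_config"))
  y <- data$observations$presence
  if (any(is.na(y))) stop("presence contains NA; simulate or load it first")
  if (length(unique(y)) < 2)
    stop("response is all-", y[1], "; the model is not identifiable ",
         "(complete separation)")
  std <- standardize_covariates(data)
  X <- build_design_matrix(std$data)
  mcmc_spec <- mcmc_settings(config, priors)

  res <- with_seed(config$seed, {
    gibbs_logistic(
      y = as.numeric(y), X = X,
      site = as.integer(data$obs_to_site - 1L),
      dist = if (config$spatial) as.matrix(dist(site_coords(data)))
             else matrix(0, 0, 0),
      spatial = config$spatial, beta_var = priors$beta_var,
      r_lower = priors$inv_phi_lower, r_upper = priors$inv_phi_upper,
      s2_shape = priors$sigma2_shape, s2_scale = priors$sigma2_scale,
      n_retain = config$n_retained, burn = config$burn_in,
      thin = config$thin, jitter = config$jitter,
      prop_sd = config$prop_sd, sample_cov = mcmc_spec$sample_cov,
      sigma2_init = mcmc_spec$sigma2_init, phi_init = mcmc_spec$phi_init)
  })

  beta <- res$beta
  colnames(beta) <- DESIGN_COLUMNS[seq_len(ncol(beta))]
  out <- list(beta = beta, spatial = config$spatial,
              sites = data$sites, std_params = std$params,
              priors = priors, config = config,
              term_names = colnames(beta),
              accept = c(beta = 1, eta = if (config$spatial) 1 else NA,
                         phi = res$accept_phi))
  if (config$spatial) {
    eta <- res$eta
    colnames(eta) <- data$sites$site_id
    out$eta <- eta
    out$sigma2 <- as.numeric(res$sigma2)
    out$phi <- as.numeric(res$phi)
  }
  structure(out, class = "buv_draws")
}

# resolve starting values / fixed-parameter mode
mcmc_settings <- function(config, priors) {
  mid_range <- (priors$inv_phi_lower + priors$inv_phi_upper) / 2
  if (!is.null(config$sigma2_fixed)) {
    list(sample_cov = FALSE,
         sigma2_init = config$sigma2_fixed,
         phi_init = if (is.null(config$phi_init)) 1 / mid_range
                    else config$phi_init)
  } else {
    list(sample_cov = TRUE,
         sigma2_init = if (is.null(config$sigma2_init)) 1
                       else config$sigma2_init,
         phi_init = if (is.null(config$phi_init)) 1 / mid_range
                    else config$phi_init)
  }
}

#' @export
print.buv_draws <- function(x, ...) {
  cat(if (x$spatial) "Spatial" else "Non-spatial",
      "Bayesian logistic fit:", nrow(x$beta), "retained draws,",
      nrow(x$sites), "sites\n")
  if (x$spatial)
    cat("  phi acceptance rate:", round(x$accept[["phi"]], 3),
        " | posterior median effective range:",
        round(median(effective_range(x$phi)), 1), "m\n")
  invisible(x)
}
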