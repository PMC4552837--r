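# Shared fixtures built in code.

# minimal valid observation table (3 deployments at 2 sites)
tiny_obs <- function() {
  data.frame(
    site_id = c("A", "A", "B"),
    easting = c(1000, 1000, 2000),
    northing = c(500, 500, 800),
    season = c("winter", "summer", "winter"),
    status = c("open", "green_new", "open"),
    depth = c(10, 10, 30),
    visibility = c(5, 8, 12),
    rock = c(1, 1, 0), kelp = c(0, 0, 1), sand = c(1, 1, 1),
    coffee_rock = c(0, 0, 0),
    presence = c(1, 0, 1),
    stringsAsFactors = FALSE)
}

tiny_csv <- function(obs = tiny_obs()) {
  path <- tempfile(fileext = ".csv")
  write.csv(obs, path, row.names = FALSE, quote = FALSE)
  path
}

# a small but fittable synthetic survey
small_survey <- function(seed = 11, n_clusters = 4, sites_per_cluster = 15,
                         sigma2 = 1, phi = 3 / 2000) {
  cfg <- sim_config(n_clusters = n_clusters,
                    sites_per_cluster = sites_per_cluster,
                    band_length = 12000, band_width = 2000,
                    sigma2_true = sigma2, phi_true = phi, seed = seed)
  simulate_survey(cfg)
}

# multivariate normal log density at x for zero mean and covariance C
mvtnorm_logd <- function(x, C) {
  L <- chol(C)
  v <- backsolve(L, x, transpose = TRUE)
  -sum(log(diag(L))) - 0.5 * sum(v^2) - 0.5 * length(x) * log(2 * pi)
}

# logit helper for fixtures
logit <- function(p) log(p / (1 - p))

# fast sampler settings for contract tests
quick_cfg <- function(spatial, n_retained = 200, burn_in = 100, thin = 1,
                      seed = 1, ...) {
  fit_config(spatial = spatial, n_retained = n_retained,
             burn_in = burn_in, thin = thin, seed = seed, ...)
}
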