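# Model evaluation: per-draw predicted probabilities, LL/MSE/AUC
# summaries, location-blocked folds, conditional (kriged) random effects
# at unobserved sites, and the full cross-validation loop.

#' Per-draw predicted presence probabilities
#'
#' For each retained draw m and observation i computes
#' `logit^-1(x_i' beta_m + eta_m(site_i))`; the spatial term is zero for
#' non-spatial fits. New data are standardized with the *training*
#' parameters stored in the draws object. For a spatial fit every site in
#' `data` must be a training site (matched by site_id and coordinates)
#' unless kriged effects are supplied via `eta_new`.
#'
#' @param draws a `buv_draws` object from [fit_model()].
#' @param data a `buv_survey` with raw covariates.
#' @param eta_new optional draws x n_new_sites matrix of spatial effects
#'   for the sites of `data` (columns in `data$sites` order), e.g. from
#'   [krige_random_effect()] applied per draw.
#' @return `n_retained` x `n_obs` matrix of probabilities in (0, 1).
#' @export
predict_probabilities <- function(draws, data, eta_new = NULL) {
  stopifnot(inherits(draws, "buv_draws"), inherits(data, "buv_survey"))
  X <- build_design_matrix(apply_standardization(data, draws$std_params))
  lin <- draws$beta %*% t(X)                       # draws x obs
  if (draws$spatial) {
    if (is.null(eta_new)) {
      key <- function(s) paste(s$site_id, s$easting, s$northing)
      idx <- match(key(data$sites), key(draws$sites))
      if (any(is.na(idx)))
        stop("data contain sites not seen in fitting; supply eta_new ",
             "from krige_random_effect()")
      eta_obs <- draws$eta[, idx, drop = FALSE][, data$obs_to_site,
                                                drop = FALSE]
    } else {
      stopifnot(nrow(eta_new) == nrow(draws$beta),
                ncol(eta_new) == nrow(data$sites))
      eta_obs <- eta_new[, data$obs_to_site, drop = FALSE]
    }
    lin <- lin + eta_obs
  }
  invlogit(lin)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly chosen presence
#' receives a higher predicted probability than a randomly chosen
#' absence, ties counted one half; identical to trapezoidal integration
#' of the ROC curve.
#'
#' @param y 0/1 response containing both classes.
#' @param p predicted probabilities (any monotone score works).
#' @return scalar in \[0, 1\].
#' @export
auc <- function(y, p) {
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: response contains a single class")
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior summaries of LL, MSE and AUC
#'
#' For each retained draw computes the Bernoulli log-likelihood, the mean
#' squared error `mean((y - p)^2)` and the ROC AUC of that draw's
#' probabilities, then summarizes each metric by its posterior mean and
#' central 95% interval.
#'
#' @param y 0/1 response.
#' @param prob_matrix draws x observations probability matrix
#'   (see [predict_probabilities()]).
#' @param level credible level for the equal-tailed interval.
#' @return data.frame with columns `metric` (LL, MSE, AUC),
#'   `posterior_mean`, `interval_low`, `interval_high`; the per-draw
#'   values are attached as attribute `"per_draw"` (draws x 3 matrix).
#' @export
metric_summaries <- function(y, prob_matrix, level = 0.95) {
  prob_matrix <- rbind(prob_matrix)
  stopifnot(ncol(prob_matrix) == length(y))
  per <- t(apply(prob_matrix, 1, function(p)
    c(LL = bernoulli_loglik(y, p), MSE = mean((y - p)^2),
      AUC = auc(y, p))))
  a <- (1 - level) / 2
  # type-6 quantiles: extreme sample quantiles are not pulled toward the
  # center at small draw counts, so intervals never tighten artificially
  # when a chain is thinned
  out <- data.frame(
    metric = colnames(per),
    posterior_mean = colMeans(per),
    interval_low = apply(per, 2, quantile, probs = a, type = 6),
    interval_high = apply(per, 2, quantile, probs = 1 - a, type = 6),
    row.names = NULL)
  attr(out, "per_draw") <- per
  out
}

#' Assign sites to cross-validation folds
#'
#' Location-blocked folds: the sites are randomly permuted under the seed
#' and dealt into `k` groups whose sizes differ by at most one; every
#' observation inherits its site's fold, so repeat visits never straddle
#' a fold boundary.
#'
#' @param data a `buv_survey` object.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic per seed.
#' @return object of class `buv_folds`: list with `k`, `site_fold`
#'   (named integer vector over sites), `obs_fold` (per observation) and
#'   `seed`.
#' @export
assign_location_folds <- function(data, k, seed = 1) {
  stopifnot(inherits(data, "buv_survey"))
  if (k < 2) stop("k must be at least 2")
  n_sites <- nrow(data$sites)
  if (n_sites < k) stop("fewer sites than folds")
  site_fold <- with_seed(seed, {
    f <- rep(seq_len(k), length.out = n_sites)
    f[order(sample.int(n_sites))]
  })
  names(site_fold) <- data$sites$site_id
  structure(list(k = as.integer(k), site_fold = site_fold,
                 obs_fold = site_fold[data$obs_to_site], seed = seed),
            class = "buv_folds")
}

#' Conditional (kriged) spatial random effect at new sites
#'
#' Given one posterior draw of the site effects and GP parameters, the
#' effect at new locations is Gaussian with mean `c' C^-1 eta_train` and
#' covariance `sigma2 R_new - c' C^-1 c`, where `C` is the training
#' covariance and `c` the cross-covariance. By default one sample is
#' drawn from that conditional; `type = "mean"` returns the conditional
#' mean (useful for surfaces and diagnostics).
#'
#' @param eta training-site effects for one draw.
#' @param sigma2,phi GP parameters for the same draw.
#' @param train_sites,new_sites two-column coordinate matrices (or
#'   data.frames with easting/northing).
#' @param jitter relative diagonal nugget for factorization.
#' @param type `"sample"` or `"mean"`.
#' @return numeric vector over new sites; for `type = "mean"` the
#'   conditional standard deviations are attached as attribute `"sd"`.
#' @export
krige_random_effect <- function(eta, sigma2, phi, train_sites, new_sites,
                                jitter = 0, type = c("sample", "mean")) {
  type <- match.arg(type)
  tr <- coord_matrix(train_sites)
  nw <- coord_matrix(new_sites)
  stopifnot(length(eta) == nrow(tr), sigma2 > 0, phi > 0)

  C <- exp_covariance(tr, sigma2, phi, jitter)
  L <- tryCatch(chol(C), error = function(e)
    stop("training covariance factorization failed; increase jitter ",
         "(duplicate or near-duplicate coordinates?)"))
  cross <- sigma2 * exp(-phi * cross_dist(nw, tr))    # n_new x n_train
  Ci_eta <- backsolve(L, backsolve(L, eta, transpose = TRUE))
  mu <- drop(cross %*% Ci_eta)
  # conditional covariance
  W <- backsolve(L, t(cross), transpose = TRUE)        # n_train x n_new
  Sig <- sigma2 * exp(-phi * cross_dist(nw, nw)) - crossprod(W)
  diag(Sig) <- pmax(diag(Sig), 0)
  if (type == "mean") {
    attr(mu, "sd") <- sqrt(diag(Sig))
    return(mu)
  }
  Sig_j <- Sig
  diag(Sig_j) <- diag(Sig_j) + sigma2 * max(jitter, 1e-10)
  Lc <- chol(Sig_j)
  mu + drop(crossprod(Lc, rnorm(nrow(nw))))
}

coord_matrix <- function(x) {
  if (is.data.frame(x) && all(c("easting", "northing") %in% names(x)))
    x <- x[, c("easting", "northing")]
  m <- as.matrix(x)
  stopifnot(ncol(m) == 2)
  storage.mode(m) <- "double"
  m
}

cross_dist <- function(a, b) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da^2 + db^2)
}

# kriged effects for every retained draw: draws x n_new matrix
krige_all_draws <- function(draws, new_sites, jitter = NULL,
                            type = "sample") {
  stopifnot(inherits(draws, "buv_draws"), draws$spatial)
  if (is.null(jitter)) jitter <- draws$config$jitter
  tr <- site_coords(list(sites = draws$sites))
  M <- nrow(draws$beta)
  out <- matrix(0, M, nrow(new_sites))
  for (m in seq_len(M)) {
    out[m, ] <- krige_random_effect(draws$eta[m, ], draws$sigma2[m],
                                    draws$phi[m], tr, new_sites,
                                    jitter = jitter, type = type)
  }
  out
}

#' Location-blocked k-fold cross-validation of both models
#'
#' For each fold, fits the spatial and non-spatial models on the
#' complementary training observations (standardization parameters are
#' re-estimated on each training split), krige-samples the spatial effect
#' at the held-out sites for every retained draw, and computes
#' out-of-sample LL, MSE and AUC posterior summaries. Held-out responses
#' are never visible to the fitting step.
#'
#' @param data a `buv_survey` dataset with presence.
#' @param priors a [prior_spec()] object.
#' @param config a [fit_config()] object; its `spatial` flag is ignored
#'   (both models are always fitted) and its seed is offset per fold.
#' @param k number of folds.
#' @param seed seed for the fold assignment (and per-fold kriging).
#' @return data.frame with columns `model`, `fold` (1..k then `"mean"`),
#'   `metric`, `posterior_mean`, `interval_low`, `interval_high`.
#'   Degenerate folds (single-class training response) are skipped with a
#'   warning.
#' @export
cross_validate <- function(data, priors = prior_spec(),
                           config = fit_config(), k = 5, seed = 1) {
  folds <- assign_location_folds(data, k, seed)
  rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(folds$obs_fold == f)
    train_idx <- which(folds$obs_fold != f)
    train <- subset_survey(data, train_idx)
    test <- subset_survey(data, test_idx)
    y_train <- train$observations$presence
    y_test <- test$observations$presence
    if (length(unique(y_train)) < 2 || length(unique(y_test)) < 2) {
      warning("fold ", f, " skipped: single-class response")
      next
    }
    for (spatial in c(FALSE, TRUE)) {
      cfg <- config
      cfg$spatial <- spatial
      cfg$seed <- config$seed + 1000L * f + as.integer(spatial)
      fit <- fit_model(train, priors, cfg)
      if (spatial) {
        eta_new <- with_seed(seed + 7919L * f,
                             krige_all_draws(fit, site_coords(test)))
        pm <- predict_probabilities(fit, test, eta_new = eta_new)
      } else {
        pm <- predict_probabilities(fit, test)
      }
      ms <- metric_summaries(y_test, pm)
      ms$model <- if (spatial) "spatial" else "nonspatial"
      ms$fold <- as.character(f)
      rows[[length(rows) + 1L]] <- ms
    }
  }
  if (!length(rows)) stop("all folds degenerate")
  out <- do.call(rbind, rows)
  means <- stats::aggregate(
    out[c("posterior_mean", "interval_low", "interval_high")],
    by = out[c("model", "metric")], FUN = mean)
  means$fold <- "mean"
  out <- rbind(out[c("model", "fold", "metric", "posterior_mean",
                     "interval_low", "interval_high")],
               means[c("model", "fold", "metric", "posterior_mean",
                       "interval_low", "interval_high")])
  rownames(out) <- NULL
  out
}
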