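test_that("AUC equals pairwise concordance with half credit for ties", {
  # hand case: 4 positive-negative pairs, 3 concordant
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.4)), "single class")

  # exhaustive concordance oracle on random small instances
  set.seed(42)
  for (i in seq_len(100)) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))    # guarantee both classes
    p <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    pos <- p[y == 1]; neg <- p[y == 0]
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    expect_equal(auc(y, p), mean(cmp))
  }
})

test_that("metric summaries match hand-computed LL and MSE", {
  y <- c(1, 0)
  ms <- metric_summaries(y, matrix(c(0.8, 0.2), nrow = 1))
  per <- attr(ms, "per_draw")
  expect_equal(unname(per[1, "LL"]), 2 * log(0.8))
  expect_equal(unname(per[1, "LL"]), -0.4463, tolerance = 1e-4)
  expect_equal(unname(per[1, "MSE"]), 0.04)
  expect_equal(ms$metric, c("LL", "MSE", "AUC"))
  # single draw: interval collapses onto the mean
  expect_equal(ms$interval_low, ms$posterior_mean)

  # perfect prediction (clipped 0/1 probabilities)
  pm <- matrix(rep(c(1 - 1e-12, 1e-12, 1 - 1e-12), 5), nrow = 5,
               byrow = TRUE)
  ms2 <- metric_summaries(c(1, 0, 1), pm)
  expect_equal(ms2$posterior_mean[ms2$metric == "LL"], 0, tolerance = 1e-9)
  expect_equal(ms2$posterior_mean[ms2$metric == "MSE"], 0, tolerance = 1e-9)
  expect_equal(ms2$posterior_mean[ms2$metric == "AUC"], 1)
})

test_that("credible intervals do not shrink when draws are subsampled", {
  sim <- small_survey(seed = 15, n_clusters = 2, sites_per_cluster = 8)
  y <- sim$data$observations$presence
  set.seed(10)
  M <- 400
  pm <- matrix(plogis(rnorm(M * length(y), qnorm(0.3 + 0.4 * y), 0.8)),
               nrow = M)
  full <- metric_summaries(y, pm)
  width_full <- full$interval_high - full$interval_low
  widths <- replicate(20, {
    sub <- pm[sample.int(M, M / 10), , drop = FALSE]
    ms <- metric_summaries(y, sub)
    ms$interval_high - ms$interval_low
  })
  expect_true(all(rowMeans(widths) >= width_full - 0.05 * width_full))
})

test_that("location-blocked folds keep repeat visits together and deal evenly", {
  sim <- small_survey(seed = 6)
  d <- sim$data
  f <- assign_location_folds(d, k = 5, seed = 3)
  # every observation inherits its site's fold
  expect_equal(unname(f$obs_fold),
               unname(f$site_fold[d$obs_to_site]))
  expect_true(all(tapply(f$obs_fold, d$observations$site_id,
                         function(v) length(unique(v))) == 1))
  # near-equal site counts: 60 sites, 5 folds -> all folds of size 12
  expect_true(max(table(f$site_fold)) - min(table(f$site_fold)) <= 1)
  # deterministic per seed
  expect_identical(f$site_fold,
                   assign_location_folds(d, 5, seed = 3)$site_fold)
  expect_false(identical(f$site_fold,
                         assign_location_folds(d, 5, seed = 4)$site_fold))
  expect_error(assign_location_folds(d, 1), "at least 2")
})

test_that("174 sites deal into fold sizes {35, 35, 35, 35, 34}", {
  d <- generate_survey(sim_config(seed = 5))
  f <- assign_location_folds(d, 5, seed = 1)
  expect_equal(sort(as.integer(table(f$site_fold))),
               c(34, 35, 35, 35, 35))
})

test_that("kriging reproduces closed-form conditional moments", {
  train <- cbind(easting = c(0, 3000), northing = c(0, 0))
  sigma2 <- 1.7; phi <- 1 / 700
  eta_tr <- c(0.9, -1.1)

  # single training point at distance d: mean e^{-phi d} eta,
  # var sigma2 (1 - e^{-2 phi d})
  for (dd in c(100, 800, 2500)) {
    m <- krige_random_effect(eta_tr[1], sigma2, phi,
                             train[1, , drop = FALSE],
                             cbind(dd, 0), type = "mean")
    rho <- exp(-phi * dd)
    expect_equal(as.numeric(m), rho * eta_tr[1], tolerance = 1e-10)
    expect_equal(unname(attr(m, "sd")), sqrt(sigma2 * (1 - rho^2)),
                 tolerance = 1e-10)
  }

  # coincident site: interpolation with zero variance
  m0 <- krige_random_effect(eta_tr, sigma2, phi, train,
                            train[2, , drop = FALSE], type = "mean")
  expect_equal(as.numeric(m0), eta_tr[2], tolerance = 1e-8)
  expect_equal(unname(attr(m0, "sd")), 0, tolerance = 1e-6)

  # far site: reversion to the prior
  mf <- krige_random_effect(eta_tr, sigma2, phi, train,
                            cbind(5e6, 0), type = "mean")
  expect_equal(as.numeric(mf), 0, tolerance = 1e-8)
  expect_equal(unname(attr(mf, "sd")), sqrt(sigma2), tolerance = 1e-6)

  # sampling mode is unbiased for the conditional mean
  set.seed(8)
  draws <- replicate(4000, krige_random_effect(
    eta_tr, sigma2, phi, train, cbind(500, 200)))
  m <- krige_random_effect(eta_tr, sigma2, phi, train, cbind(500, 200),
                           type = "mean")
  expect_lt(abs(mean(draws) - as.numeric(m)),
            3 * sd(draws) / sqrt(length(draws)))
  expect_lt(abs(sd(draws) - attr(m, "sd")), 0.05)
})

test_that("predicted probability matrix matches the linear predictor", {
  sim <- small_survey(seed = 23, n_clusters = 2, sites_per_cluster = 8)
  d <- sim$data
  fit <- fit_model(d, config = quick_cfg(TRUE, n_retained = 30,
                                         burn_in = 30, seed = 4))
  pm <- predict_probabilities(fit, d)
  expect_equal(dim(pm), c(30, nrow(d$observations)))
  expect_true(all(pm > 0 & pm < 1))
  # recompute one draw by hand
  X <- build_design_matrix(apply_standardization(d, fit$std_params))
  m <- 17
  by_hand <- plogis(drop(X %*% fit$beta[m, ]) +
                      fit$eta[m, d$obs_to_site])
  expect_equal(unname(pm[m, ]), unname(by_hand), tolerance = 1e-12)
  # beta = 0, eta = 0 draw gives exactly 1/2
  fit0 <- fit
  fit0$beta[1, ] <- 0
  fit0$eta[1, ] <- 0
  expect_equal(unname(predict_probabilities(fit0, d)[1, ]),
               rep(0.5, nrow(d$observations)))
  # unseen sites require kriged effects
  other <- small_survey(seed = 99, n_clusters = 2, sites_per_cluster = 4)
  expect_error(predict_probabilities(fit, other$data), "krige")
})

test_that("cross-validation reports k folds plus a mean row per model and metric", {
  sim <- small_survey(seed = 33, n_clusters = 3, sites_per_cluster = 10)
  cv <- cross_validate(sim$data, prior_spec(),
                       quick_cfg(TRUE, n_retained = 60, burn_in = 40),
                       k = 3, seed = 2)
  expect_equal(nrow(cv), 2 * 3 * (3 + 1))
  expect_setequal(unique(cv$fold), c("1", "2", "3", "mean"))
  expect_setequal(unique(cv$model), c("nonspatial", "spatial"))
  expect_setequal(unique(cv$metric), c("LL", "MSE", "AUC"))
  # the mean row is the average of the per-fold rows
  for (mod in c("nonspatial", "spatial")) {
    sub <- cv[cv$model == mod & cv$metric == "AUC", ]
    expect_equal(sub$posterior_mean[sub$fold == "mean"],
                 mean(sub$posterior_mean[sub$fold != "mean"]))
  }
  expect_true(all(cv$posterior_mean[cv$metric == "AUC"] >= 0 &
                    cv$posterior_mean[cv$metric == "AUC"] <= 1))
  expect_true(all(cv$posterior_mean[cv$metric == "LL"] <= 0))
  expect_true(all(cv$posterior_mean[cv$metric == "MSE"] >= 0))
})
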