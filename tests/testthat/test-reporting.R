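test_that("coefficient summaries flag significance and transform to odds ratios", {
  sim <- small_survey(seed = 41, n_clusters = 3, sites_per_cluster = 10)
  fit <- fit_model(sim$data, config = quick_cfg(FALSE, n_retained = 400,
                                                burn_in = 150, seed = 2))
  cs <- summarize_coefficients(fit)
  expect_equal(cs$name, colnames(fit$beta))
  expect_equal(cs$significant, cs$ci_low > 0 | cs$ci_high < 0)
  # OR interval endpoints are exp of the beta interval endpoints
  expect_equal(cs$or_low, exp(cs$ci_low))
  expect_equal(cs$or_high, exp(cs$ci_high))
  # posterior mean of exp(beta) dominates exp(posterior mean) (Jensen)
  expect_true(all(cs$or_mean >= cs$or_at_mean - 1e-12))

  # degenerate draws at zero: OR exactly 1, not significant
  fit0 <- fit
  fit0$beta <- matrix(0, 50, 10, dimnames = list(NULL, colnames(fit$beta)))
  cs0 <- summarize_coefficients(fit0)
  expect_true(all(cs0$or_mean == 1 & cs0$or_low == 1 & cs0$or_high == 1))
  expect_false(any(cs0$significant))
})

test_that("HPD interval is the shortest window with the requested mass", {
  expect_equal(hpd_interval(c(5, 1, 3), level = 1), c(1, 5))
  # exhaustive 4-point windows of (1,2,3,4,100): (1,4) is shortest
  expect_equal(hpd_interval(c(1, 2, 3, 4, 100), level = 0.8), c(1, 4))
  # large normal sample: endpoints near +-1.96
  set.seed(5)
  x <- rnorm(1e5)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_error(hpd_interval(numeric(0)), "at least 2")

  # HPD lies inside the sample range and is never wider than the
  # central interval at the same level
  set.seed(6)
  for (i in 1:25) {
    s <- rgamma(500, shape = runif(1, 0.5, 5))
    h <- hpd_interval(s, 0.9)
    q <- quantile(s, c(0.05, 0.95), names = FALSE)
    expect_gte(h[1], min(s)); expect_lte(h[2], max(s))
    expect_lte(h[2] - h[1], q[2] - q[1] + 1e-12)
  }
})

test_that("effective range summary transforms phi draws correctly", {
  sim <- small_survey(seed = 45, n_clusters = 3, sites_per_cluster = 8)
  fit <- fit_model(sim$data, config = quick_cfg(TRUE, n_retained = 201,
                                                burn_in = 100, seed = 3))
  er <- effective_range_summary(fit)
  # monotone decreasing transform: the median commutes (odd draw count,
  # so the sample median is an order statistic)
  expect_equal(er$median, 3 / median(fit$phi))
  expect_equal(er$mean, mean(3 / fit$phi))
  expect_lte(er$hpd_low, er$median)
  expect_gte(er$hpd_high, er$median)

  # degenerate posterior: all summaries collapse
  fitc <- fit
  fitc$phi <- rep(0.003, 50)
  erc <- effective_range_summary(fitc)
  expect_equal(unlist(erc), c(median = 1000, mean = 1000,
                              hpd_low = 1000, hpd_high = 1000))

  ns <- fit_model(sim$data, config = quick_cfg(FALSE, seed = 1))
  expect_error(effective_range_summary(ns), "spatial")
})

test_that("effect surface interpolates site effects and masks distant cells", {
  sim <- small_survey(seed = 47, n_clusters = 2, sites_per_cluster = 8)
  fit <- fit_model(sim$data, config = quick_cfg(TRUE, n_retained = 80,
                                                burn_in = 60, seed = 5))
  s1 <- site_coords(sim$data)[1, ]
  ext <- c(s1[1] - 260, s1[1] + 260, s1[2] - 260, s1[2] + 260)
  surf <- effect_surface(fit, cell_size = 20, extent = unname(ext),
                         cutoff = 5000)
  expect_s3_class(surf, "buv_surface")
  # cell containing a site: close to that site's posterior mean eta
  i <- which.min(abs(surf$ycenters - s1[2]))
  j <- which.min(abs(surf$xcenters - s1[1]))
  eta_bar <- mean(fit$eta[, 1])
  mc_se <- sd(fit$eta[, 1]) / sqrt(nrow(fit$eta))
  expect_lt(abs(surf$values[i, j] - eta_bar), max(2 * mc_se, 0.05))

  # cells beyond the cutoff are masked
  far <- effect_surface(fit, cell_size = 500, cutoff = 300)
  expect_true(any(is.na(far$values)))
  centers <- expand.grid(x = far$xcenters, y = far$ycenters)
  dmin <- apply(buvspatial:::cross_dist(as.matrix(centers),
                                        site_coords(sim$data)), 1, min)
  expect_true(all(is.na(t(far$values))[dmin > 300]))
  expect_true(all(!is.na(t(far$values))[dmin <= 300]))

  # surface values equal a direct per-draw kriging recomputation
  keep <- which(!is.na(t(surf$values)))
  pick <- sample(keep, 10)
  centers2 <- as.matrix(expand.grid(x = surf$xcenters, y = surf$ycenters))
  for (cell in pick) {
    vals <- vapply(seq_len(nrow(fit$beta)), function(m)
      as.numeric(krige_random_effect(
        fit$eta[m, ], fit$sigma2[m], fit$phi[m],
        site_coords(sim$data), centers2[cell, , drop = FALSE],
        jitter = fit$config$jitter, type = "mean")), numeric(1))
    expect_equal(t(surf$values)[cell], mean(vals), tolerance = 1e-8)
  }
  expect_error(effect_surface(fit, 100, extent = c(0, 0, 0, 0)), "extent")
})

test_that("draws and surfaces round-trip through their text formats", {
  sim <- small_survey(seed = 51, n_clusters = 2, sites_per_cluster = 6)
  fit <- fit_model(sim$data, config = quick_cfg(TRUE, n_retained = 40,
                                                burn_in = 30, seed = 6))
  p1 <- tempfile(fileext = ".tsv")
  write_draws(fit, p1)
  back <- read_draws(p1)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$eta, fit$eta, tolerance = 1e-12)
  expect_equal(back$phi, fit$phi, tolerance = 1e-12)
  expect_equal(back$sites, fit$sites)
  expect_equal(back$std_params$depth_mean, fit$std_params$depth_mean)

  # byte-identical reports given identical draws
  p2 <- tempfile(fileext = ".tsv")
  write_draws(fit, p2)
  expect_identical(readLines(p1), readLines(p2))

  surf <- effect_surface(fit, cell_size = 1000, cutoff = 2000,
                         n_draws = 10)
  g1 <- tempfile(fileext = ".asc")
  write_surface_grid(surf, g1)
  lines <- readLines(g1)
  expect_match(lines[1], "^ncols")
  expect_match(lines[6], "^NODATA_value -9999")
  expect_equal(length(lines), 6 + nrow(surf$values))
  # kriging from a reloaded draws file gives the same summaries
  er1 <- effective_range_summary(fit)
  er2 <- effective_range_summary(back)
  expect_equal(er1$median, er2$median, tolerance = 1e-12)
})
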