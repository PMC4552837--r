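# Synthetic BUV surveys: clustered sites in an elongated coastal band,
# spatially clumped habitat, GP-driven presence.

#' Default regression coefficients for simulation
#'
#' Log odds ratios on the standardized design-matrix scale, in the column
#' order of [build_design_matrix()]. The non-intercept entries are set
#' near estimates typical of coastal snapper BUV studies (strong positive
#' kelp and coffee-rock effects, weak zone effects); the intercept places
#' the baseline open-zone summer deployment at roughly a 20% presence
#' probability.
#'
#' @return named numeric 10-vector.
#' @export
default_beta <- function() {
  c(intercept = -1.4, green_old = log(0.67), green_new = log(0.89),
    depth_std = log(1.32), rock = log(1.72), kelp = log(9.96),
    sand = log(0.99), coffee_rock = log(3.18), winter = log(1.89),
    visibility_std = log(1.36))
}

#' Simulation configuration
#'
#' Defaults emulate the scale of a clustered coastal BUV survey: 6 site
#' clusters of 29 sites (174 sites) strung along a 30 km x 3 km band,
#' minimum inter-site distance 20 m, five deployment periods (3 winters,
#' 2 summers) each visited with probability 0.62, which yields about 536
#' observations in expectation. Habitat indicators are spatially clumped
#' thresholded Gaussian fields. No-take ("green") zones are axis-aligned
#' rectangles along the band; the newer zones only take effect from the
#' third period, mimicking a mid-survey re-zoning.
#'
#' @param n_clusters number of site clusters.
#' @param sites_per_cluster sites per cluster.
#' @param cluster_spread sd (m) of site scatter around a cluster center.
#' @param band_length,band_width extent (m) of the coastal band.
#' @param min_site_distance minimum pairwise site distance (m).
#' @param n_periods number of deployment periods (alternating
#'   winter/summer, starting in winter).
#' @param visit_prob per-period probability a site is visited; every site
#'   gets at least one visit.
#' @param habitat_prevalence named marginal probabilities for rock, kelp,
#'   sand, coffee_rock.
#' @param habitat_clump_range effective range (m) of habitat clumping.
#' @param green_old_frac,green_new_frac fractions of the band covered by
#'   old and new no-take rectangles.
#' @param depth_range uniform range (m) of per-site depth.
#' @param visibility_mean,visibility_sd per-deployment visibility (m),
#'   normal truncated below at 1 m.
#' @param beta_true true coefficients (see [default_beta()]).
#' @param sigma2_true GP partial sill (logit scale variance).
#' @param phi_true GP decay (1/m); default gives a 2000 m effective range.
#' @param seed integer seed.
#' @return object of class `buv_sim_config` (a named list).
#' @export
sim_config <- function(n_clusters = 6, sites_per_cluster = 29,
                       cluster_spread = 400, band_length = 30000,
                       band_width = 3000, min_site_distance = 20,
                       n_periods = 5, visit_prob = 0.62,
                       habitat_prevalence = c(rock = 0.35, kelp = 0.25,
                                              sand = 0.60,
                                              coffee_rock = 0.15),
                       habitat_clump_range = 1500,
                       green_old_frac = 0.20, green_new_frac = 0.28,
                       depth_range = c(8, 47), visibility_mean = 8,
                       visibility_sd = 3, beta_true = default_beta(),
                       sigma2_true = 1, phi_true = 3 / 2000, seed = 1) {
  cfg <- list(n_clusters = n_clusters, sites_per_cluster = sites_per_cluster,
              cluster_spread = cluster_spread, band_length = band_length,
              band_width = band_width, min_site_distance = min_site_distance,
              n_periods = n_periods, visit_prob = visit_prob,
              habitat_prevalence = habitat_prevalence,
              habitat_clump_range = habitat_clump_range,
              green_old_frac = green_old_frac,
              green_new_frac = green_new_frac, depth_range = depth_range,
              visibility_mean = visibility_mean,
              visibility_sd = visibility_sd, beta_true = beta_true,
              sigma2_true = sigma2_true, phi_true = phi_true, seed = seed)
  stopifnot(all(habitat_prevalence >= 0 & habitat_prevalence <= 1),
            visit_prob >= 0, visit_prob <= 1, sigma2_true >= 0,
            phi_true > 0, min_site_distance >= 0, n_clusters >= 1,
            sites_per_cluster >= 1, n_periods >= 1)
  structure(cfg, class = "buv_sim_config")
}

# Place sites by rejection sampling around cluster centers; error after
# `retries` failed proposals per site (infeasible packing).
place_sites <- function(cfg, retries = 1000) {
  n_sites <- cfg$n_clusters * cfg$sites_per_cluster
  centers <- cbind(runif(cfg$n_clusters, 0, cfg$band_length),
                   runif(cfg$n_clusters, 0, cfg$band_width))
  xs <- numeric(n_sites); ys <- numeric(n_sites)
  k <- 0
  for (cl in seq_len(cfg$n_clusters)) {
    for (j in seq_len(cfg$sites_per_cluster)) {
      placed <- FALSE
      for (try in seq_len(retries)) {
        x <- rnorm(1, centers[cl, 1], cfg$cluster_spread)
        y <- rnorm(1, centers[cl, 2], cfg$cluster_spread)
        if (x < 0 || x > cfg$band_length || y < 0 || y > cfg$band_width)
          next
        if (k > 0) {
          d2 <- (xs[seq_len(k)] - x)^2 + (ys[seq_len(k)] - y)^2
          if (min(d2) < cfg$min_site_distance^2) next
        }
        k <- k + 1; xs[k] <- x; ys[k] <- y
        placed <- TRUE
        break
      }
      if (!placed)
        stop("site placement infeasible: could not fit ", n_sites,
             " sites at minimum distance ", cfg$min_site_distance,
             " m after ", retries, " retries")
    }
  }
  data.frame(site_id = sprintf("s%03d", seq_len(n_sites)),
             easting = xs, northing = ys, stringsAsFactors = FALSE)
}

# One zero-mean unit-variance GP draw at coords, exponential correlation
# with the given effective range; returns a vector.
gp_draw <- function(coords, effective_range, jitter = 1e-8) {
  phi <- 3 / effective_range
  R <- exp(-phi * as.matrix(dist(coords)))
  diag(R) <- 1 + jitter
  L <- chol(R)
  drop(crossprod(L, rnorm(nrow(coords))))
}

# Axis-aligned zone rectangles: x-intervals of the band. Old zones are
# green throughout; new zones flip from open to green_new at period 3.
zone_status <- function(x, period, cfg) {
  L <- cfg$band_length
  fo <- cfg$green_old_frac / 2
  fn <- cfg$green_new_frac / 2
  in_old <- (x >= 0.05 * L & x < (0.05 + fo) * L) |
    (x >= 0.60 * L & x < (0.60 + fo) * L)
  in_new <- (x >= (0.05 + fo) * L & x < (0.05 + fo + fn) * L) |
    (x >= (0.60 + fo) * L & x < (0.60 + fo + fn) * L)
  status <- rep("open", length(x))
  status[in_old] <- "green_old"
  status[in_new & period >= 3] <- "green_new"
  status
}

#' Generate a synthetic BUV survey design (presence unset)
#'
#' Sites are placed in clusters inside an elongated band subject to the
#' minimum inter-site distance; each site is revisited across alternating
#' winter/summer periods; habitat indicators are drawn by thresholding
#' independent spatially correlated Gaussian fields so each habitat has
#' its configured marginal prevalence but is clumped in space.
#'
#' @param config a [sim_config()] object.
#' @return a `buv_survey` dataset with `presence = NA`; pass it to
#'   [simulate_presence()] (or use [simulate_survey()]).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "buv_sim_config"))
  with_seed(config$seed, {
    sites <- place_sites(config)
    coords <- as.matrix(sites[, c("easting", "northing")])
    n_sites <- nrow(sites)

    # spatially clumped habitat: threshold a unit GP at the prevalence
    # quantile so the marginal frequency matches the configured value
    hab <- sapply(names(config$habitat_prevalence), function(h) {
      z <- gp_draw(coords, config$habitat_clump_range)
      as.numeric(z > qnorm(1 - config$habitat_prevalence[[h]]))
    })
    depth <- runif(n_sites, config$depth_range[1], config$depth_range[2])

    seasons <- rep(c("winter", "summer"), length.out = config$n_periods)
    rows <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      visited <- runif(config$n_periods) < config$visit_prob
      if (!any(visited)) visited[sample.int(config$n_periods, 1)] <- TRUE
      periods <- which(visited)
      vis <- pmax(1, rnorm(length(periods), config$visibility_mean,
                           config$visibility_sd))
      rows[[s]] <- data.frame(
        site_id = sites$site_id[s], easting = sites$easting[s],
        northing = sites$northing[s], season = seasons[periods],
        status = zone_status(rep(sites$easting[s], length(periods)),
                             periods, config),
        depth = depth[s], visibility = vis,
        rock = unname(hab[s, "rock"]), kelp = unname(hab[s, "kelp"]),
        sand = unname(hab[s, "sand"]),
        coffee_rock = unname(hab[s, "coffee_rock"]),
        presence = NA_real_, stringsAsFactors = FALSE)
    }
    survey_dataset(do.call(rbind, rows))
  })
}

#' Simulate presence from the spatial logistic model
#'
#' Draws one spatial random effect per unique site from a zero-mean GP
#' with exponential covariance `sigma2 * exp(-phi * d)`, then draws each
#' observation independently as Bernoulli(logit^-1(x'beta + eta_site)).
#' Depth and visibility are standardized internally (the coefficients are
#' on the standardized scale).
#'
#' @param data a `buv_survey` dataset (presence may be unset).
#' @param beta 10-vector of coefficients in [build_design_matrix()] order.
#' @param sigma2 GP variance (0 switches the spatial effect off).
#' @param phi GP decay parameter (1/m).
#' @param seed integer seed; a fixed seed reproduces draws exactly.
#' @return list with `data` (presence filled in), `presence`, `eta_true`
#'   (named by site_id) and `prob` (per-observation true probabilities).
#' @export
simulate_presence <- function(data, beta, sigma2, phi, seed = 1) {
  stopifnot(inherits(data, "buv_survey"), length(beta) == 10,
            sigma2 >= 0, phi > 0)
  std <- standardize_covariates(data)
  X <- build_design_matrix(std$data)
  with_seed(seed, {
    n_sites <- nrow(data$sites)
    if (sigma2 > 0) {
      eta <- sqrt(sigma2) * gp_draw(site_coords(data), 3 / phi)
    } else {
      eta <- rep(0, n_sites)
    }
    names(eta) <- data$sites$site_id
    lin <- drop(X %*% beta) + eta[data$obs_to_site]
    if (any(!is.finite(lin))) stop("non-finite linear predictor")
    prob <- invlogit(lin)
    presence <- rbinom(length(prob), 1, prob)
    out <- data
    out$observations$presence <- presence
    list(data = out, presence = presence, eta_true = eta, prob = prob)
  })
}

#' Generate a complete synthetic survey
#'
#' [generate_survey()] followed by [simulate_presence()] at the
#' configuration's true parameters.
#'
#' @param config a [sim_config()] object.
#' @return as [simulate_presence()], plus `config`.
#' @export
simulate_survey <- function(config) {
  design <- generate_survey(config)
  sim <- simulate_presence(design, config$beta_true, config$sigma2_true,
                           config$phi_true, seed = config$seed + 1L)
  sim$config <- config
  sim
}
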