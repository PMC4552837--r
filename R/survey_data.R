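# Survey tables: reading, validation, standardization, design matrix.

SURVEY_COLUMNS <- c("site_id", "easting", "northing", "season", "status",
                    "depth", "visibility", "rock", "kelp", "sand",
                    "coffee_rock", "presence")
STATUS_LEVELS <- c("open", "green_old", "green_new")
SEASON_LEVELS <- c("winter", "summer")
HABITAT_COLUMNS <- c("rock", "kelp", "sand", "coffee_rock")

DESIGN_COLUMNS <- c("intercept", "green_old", "green_new", "depth_std",
                    "rock", "kelp", "sand", "coffee_rock", "winter",
                    "visibility_std")

#' Construct a validated BUV survey dataset
#'
#' Bundles per-deployment observations with the deduplicated site table and
#' the observation-to-site index. One site is one unique `site_id`, whose
#' coordinates must be constant across repeat visits; distinct sites at
#' identical coordinates share a spatial random effect and are rejected
#' here so that the GP covariance stays non-singular.
#'
#' @param observations data.frame with columns `site_id`, `easting`,
#'   `northing` (UTM meters), `season` (`winter`/`summer`), `status`
#'   (`open`/`green_old`/`green_new`), `depth` (m), `visibility` (m),
#'   binary habitat indicators `rock`, `kelp`, `sand`, `coffee_rock`
#'   (1 = habitat covers at least 5% of the site), and `presence`
#'   (0/1 response; may be `NA` for not-yet-simulated surveys).
#' @return object of class `buv_survey`: list with `observations`,
#'   `sites` (site_id, easting, northing) and `obs_to_site` (integer index
#'   of each observation's row in `sites`).
#' @export
survey_dataset <- function(observations) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  missing <- setdiff(SURVEY_COLUMNS, names(obs))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  obs <- obs[SURVEY_COLUMNS]
  obs$site_id <- as.character(obs$site_id)

  bad <- which(!obs$status %in% STATUS_LEVELS)
  if (length(bad))
    stop(sprintf("unrecognized status '%s' in row %d (expected one of %s)",
                 obs$status[bad[1]], bad[1],
                 paste(STATUS_LEVELS, collapse = ", ")))
  bad <- which(!obs$season %in% SEASON_LEVELS)
  if (length(bad))
    stop(sprintf("unrecognized season '%s' in row %d (expected one of %s)",
                 obs$season[bad[1]], bad[1],
                 paste(SEASON_LEVELS, collapse = ", ")))
  for (h in HABITAT_COLUMNS) {
    if (!all(obs[[h]] %in% c(0, 1)))
      stop("habitat indicator '", h, "' must be 0/1")
  }
  if (!all(is.na(obs$presence) | obs$presence %in% c(0, 1)))
    stop("presence must be 0/1 (or NA before simulation)")
  if (any(!is.finite(obs$depth)) || any(obs$depth <= 0))
    stop("depth must be positive")
  if (any(!is.finite(obs$visibility)) || any(obs$visibility <= 0))
    stop("visibility must be positive")

  # site table: coordinates must be constant within a site_id
  key <- paste(obs$site_id)
  first <- !duplicated(key)
  sites <- data.frame(site_id = obs$site_id[first],
                      easting = obs$easting[first],
                      northing = obs$northing[first],
                      stringsAsFactors = FALSE)
  idx <- match(key, sites$site_id)
  if (any(obs$easting != sites$easting[idx] |
            obs$northing != sites$northing[idx])) {
    bad <- which(obs$easting != sites$easting[idx] |
                   obs$northing != sites$northing[idx])[1]
    stop(sprintf("site '%s' appears with conflicting coordinates (row %d)",
                 obs$site_id[bad], bad))
  }
  coord_key <- paste(sites$easting, sites$northing)
  if (anyDuplicated(coord_key))
    stop("distinct site_ids share identical coordinates; ",
         "merge them into one site")

  structure(list(observations = obs, sites = sites, obs_to_site = idx),
            class = "buv_survey")
}

#' @export
print.buv_survey <- function(x, ...) {
  cat("BUV survey dataset:", nrow(x$observations), "observations at",
      nrow(x$sites), "sites\n")
  if (!all(is.na(x$observations$presence)))
    cat("  presence rate:",
        round(mean(x$observations$presence, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Read a BUV survey table from CSV
#'
#' Expects the 12-column schema written by [write_survey_csv()]:
#' `site_id, easting, northing, season, status, depth, visibility, rock,
#' kelp, sand, coffee_rock, presence`. Comma-separated, UTF-8, header
#' required. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return a [survey_dataset()] object.
#' @export
load_survey_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  survey_dataset(obs)
}

#' Write a BUV survey table to CSV
#'
#' Emits the same schema [load_survey_csv()] reads, so valid datasets
#' round-trip.
#'
#' @param data a `buv_survey` object.
#' @param path output path.
#' @export
write_survey_csv <- function(data, path) {
  stopifnot(inherits(data, "buv_survey"))
  write.csv(data$observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize depth and visibility
#'
#' Centers and scales the two continuous covariates to mean 0, sample
#' standard deviation 1 (n - 1 denominator), storing the location/scale
#' parameters so held-out data can be transformed with the training
#' parameters.
#'
#' @param data a `buv_survey` object with raw depth and visibility.
#' @return list with `data` (covariates standardized in place) and
#'   `params` (class `buv_standardization`: depth_mean, depth_sd,
#'   visibility_mean, visibility_sd, in meters).
#' @export
standardize_covariates <- function(data) {
  stopifnot(inherits(data, "buv_survey"))
  obs <- data$observations
  params <- structure(list(depth_mean = mean(obs$depth),
                           depth_sd = sd(obs$depth),
                           visibility_mean = mean(obs$visibility),
                           visibility_sd = sd(obs$visibility)),
                      class = "buv_standardization")
  if (!is.finite(params$depth_sd) || params$depth_sd == 0)
    stop("depth is constant; cannot standardize")
  if (!is.finite(params$visibility_sd) || params$visibility_sd == 0)
    stop("visibility is constant; cannot standardize")
  list(data = apply_standardization(data, params), params = params)
}

#' Apply stored standardization parameters to a dataset
#'
#' @param data a `buv_survey` object with raw covariates.
#' @param params a `buv_standardization` object from
#'   [standardize_covariates()].
#' @return the dataset with depth and visibility replaced by their
#'   standardized values.
#' @export
apply_standardization <- function(data, params) {
  stopifnot(inherits(data, "buv_survey"),
            inherits(params, "buv_standardization"))
  out <- data
  out$observations$depth <-
    (data$observations$depth - params$depth_mean) / params$depth_sd
  out$observations$visibility <-
    (data$observations$visibility - params$visibility_mean) /
    params$visibility_sd
  attr(out, "standardized") <- TRUE
  out
}

#' Build the fixed-effects design matrix
#'
#' Ten columns in fixed order: intercept, green_old, green_new, depth_std,
#' rock, kelp, sand, coffee_rock, winter, visibility_std. The baseline
#' level is an open-zone summer deployment. Depth and visibility are taken
#' as given, so standardize first ([standardize_covariates()]).
#'
#' @param data a `buv_survey` object (covariates already standardized).
#' @return numeric matrix, `n_obs` x 10, with column names as above.
#' @export
build_design_matrix <- function(data) {
  stopifnot(inherits(data, "buv_survey"))
  obs <- data$observations
  X <- cbind(intercept = 1,
             green_old = as.numeric(obs$status == "green_old"),
             green_new = as.numeric(obs$status == "green_new"),
             depth_std = obs$depth,
             rock = obs$rock,
             kelp = obs$kelp,
             sand = obs$sand,
             coffee_rock = obs$coffee_rock,
             winter = as.numeric(obs$season == "winter"),
             visibility_std = obs$visibility)
  storage.mode(X) <- "double"
  X
}

# n_sites x 2 coordinate matrix
site_coords <- function(data) {
  as.matrix(data$sites[, c("easting", "northing")])
}

# subset a survey by observation indices (sites rebuilt)
subset_survey <- function(data, idx) {
  survey_dataset(data$observations[idx, , drop = FALSE])
}
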