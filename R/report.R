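# Posterior summarization and reporting.

#' Summarize regression coefficients and odds ratios
#'
#' Per coefficient: posterior mean, central credible interval,
#' significance flag (interval excludes 0), and odds-ratio scale
#' summaries. Two odds-ratio point conventions are emitted side by side:
#' `or_mean` is the posterior mean of `exp(beta)` and `or_at_mean` is
#' `exp` of the posterior mean; they differ noticeably for skewed
#' posteriors (the mean of a right-skewed lognormal exceeds `exp` of its
#' mean). Interval endpoints are `exp` of the beta quantiles, i.e. the
#' quantile-equivariant convention.
#'
#' @param draws a `buv_draws` object.
#' @param level credible level.
#' @return data.frame, one row per coefficient: `name`, `posterior_mean`,
#'   `ci_low`, `ci_high`, `significant`, `or_mean`, `or_at_mean`,
#'   `or_low`, `or_high`.
#' @export
summarize_coefficients <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "buv_draws"), nrow(draws$beta) >= 1)
  a <- (1 - level) / 2
  q <- apply(draws$beta, 2, quantile, probs = c(a, 1 - a))
  m <- colMeans(draws$beta)
  data.frame(name = colnames(draws$beta),
             posterior_mean = m,
             ci_low = q[1, ], ci_high = q[2, ],
             significant = q[1, ] > 0 | q[2, ] < 0,
             or_mean = colMeans(exp(draws$beta)),
             or_at_mean = exp(m),
             or_low = exp(q[1, ]), or_high = exp(q[2, ]),
             row.names = NULL)
}

#' Highest posterior density interval
#'
#' The shortest contiguous window of the sorted sample containing
#' `ceiling(level * n)` points.
#'
#' @param samples numeric vector (length >= 2).
#' @param level coverage fraction in (0, 1].
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2) stop("need at least 2 finite samples")
  stopifnot(level > 0, level <= 1)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Posterior summary of the effective spatial range
#'
#' Transforms each phi draw to its effective range 3/phi and reports the
#' posterior median, mean and HPD interval. The transform is monotone
#' decreasing, so the median equals `3 / median(phi)`; the right-skewed
#' shape of the range posterior makes median + HPD the preferred summary.
#'
#' @param draws a spatial `buv_draws` object.
#' @param level HPD coverage.
#' @return list with `median`, `mean`, `hpd_low`, `hpd_high` (meters).
#' @export
effective_range_summary <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "buv_draws"))
  if (!draws$spatial || is.null(draws$phi))
    stop("effective range requires a spatial fit")
  er <- effective_range(draws$phi)
  h <- if (length(er) >= 2) hpd_interval(er, level) else c(er, er)
  list(median = median(er), mean = mean(er), hpd_low = h[1],
       hpd_high = h[2])
}

#' Posterior-mean spatial effect surface on a square grid
#'
#' Evaluates, at each grid-cell center, the posterior mean over retained
#' draws of the kriged conditional mean of the spatial random effect.
#' Cells farther than `cutoff` from every site are masked (`NA`): beyond
#' the effective range the conditional mean reverts to zero and mapping
#' it would be misleading, so the cutoff defaults to the posterior median
#' effective range.
#'
#' @param draws a spatial `buv_draws` object.
#' @param cell_size cell edge length (m), e.g. 500 for an overview map or
#'   100 for a subregion.
#' @param extent `c(xmin, xmax, ymin, ymax)`; default pads the site
#'   bounding box by one cell.
#' @param cutoff mask distance (m).
#' @param n_draws optionally thin to this many evenly spaced draws.
#' @return object of class `buv_surface`: list with `cell_size`, `origin`
#'   (lower-left corner), `values` (ny x nx matrix, row 1 = southernmost
#'   row; `NA` = masked), `xcenters`, `ycenters`, `cutoff`.
#' @export
effect_surface <- function(draws, cell_size, extent = NULL, cutoff = NULL,
                           n_draws = NULL) {
  stopifnot(inherits(draws, "buv_draws"))
  if (!draws$spatial) stop("effect surface requires a spatial fit")
  stopifnot(cell_size > 0)
  coords <- site_coords(list(sites = draws$sites))
  if (is.null(extent))
    extent <- c(min(coords[, 1]) - cell_size, max(coords[, 1]) + cell_size,
                min(coords[, 2]) - cell_size, max(coords[, 2]) + cell_size)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("empty extent")
  if (is.null(cutoff))
    cutoff <- median(effective_range(draws$phi))
  nx <- max(1L, ceiling((extent[2] - extent[1]) / cell_size))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / cell_size))
  xc <- extent[1] + (seq_len(nx) - 0.5) * cell_size
  yc <- extent[3] + (seq_len(ny) - 0.5) * cell_size
  centers <- cbind(easting = rep(xc, times = ny),
                   northing = rep(yc, each = nx))
  dmin <- apply(cross_dist(centers, coords), 1, min)
  keep <- dmin <= cutoff
  vals <- rep(NA_real_, nrow(centers))
  if (any(keep)) {
    sub <- draws
    if (!is.null(n_draws) && n_draws < nrow(draws$beta)) {
      pick <- unique(round(seq(1, nrow(draws$beta), length.out = n_draws)))
      sub$beta <- draws$beta[pick, , drop = FALSE]
      sub$eta <- draws$eta[pick, , drop = FALSE]
      sub$sigma2 <- draws$sigma2[pick]
      sub$phi <- draws$phi[pick]
    }
    km <- krige_all_draws(sub, centers[keep, , drop = FALSE],
                          type = "mean")
    vals[keep] <- colMeans(km)
  }
  structure(list(cell_size = cell_size,
                 origin = c(extent[1], extent[3]),
                 values = matrix(vals, nrow = ny, ncol = nx, byrow = TRUE),
                 xcenters = xc, ycenters = yc, cutoff = cutoff),
            class = "buv_surface")
}

#' Write a surface as a headered ASCII grid
#'
#' ESRI ASCII-grid layout: `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header lines followed by row-major values,
#' first line = northernmost row.
#'
#' @param surface a `buv_surface` object.
#' @param path output path.
#' @param nodata value written for masked cells.
#' @export
write_surface_grid <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "buv_surface"))
  v <- surface$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", surface$origin[1]),
               paste("yllcorner", surface$origin[2]),
               paste("cellsize", surface$cell_size),
               paste("NODATA_value", nodata)), con)
  # row 1 of `values` is the southernmost row; ascii grids go north-first
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Persist posterior draws as a tab-separated table
#'
#' One row per retained draw; columns `beta_0 ... beta_9`, and for
#' spatial fits `sigma2`, `phi` and `eta_<site_id>`. Metadata needed to
#' reuse the draws (site coordinates, standardization parameters, prior
#' and sampler settings) is stored in `#`-prefixed header lines, so
#' [read_draws()] restores a working `buv_draws` object.
#'
#' @param draws a `buv_draws` object.
#' @param path output path (TSV).
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "buv_draws"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- draws$std_params
  writeLines(c(
    sprintf("# buvspatial draws v1 spatial=%d", as.integer(draws$spatial)),
    sprintf("# std %.15g %.15g %.15g %.15g", p$depth_mean, p$depth_sd,
            p$visibility_mean, p$visibility_sd),
    sprintf("# priors %.15g %.15g %.15g %.15g %.15g",
            draws$priors$beta_var, draws$priors$inv_phi_lower,
            draws$priors$inv_phi_upper, draws$priors$sigma2_shape,
            draws$priors$sigma2_scale),
    sprintf("# accept_phi %.15g", draws$accept[["phi"]]),
    sprintf("# site %s %.15g %.15g", draws$sites$site_id,
            draws$sites$easting, draws$sites$northing)), con)
  tab <- as.data.frame(draws$beta)
  names(tab) <- paste0("beta_", seq_len(ncol(draws$beta)) - 1L)
  if (draws$spatial) {
    tab$sigma2 <- draws$sigma2
    tab$phi <- draws$phi
    eta <- as.data.frame(draws$eta)
    names(eta) <- paste0("eta_", colnames(draws$eta))
    tab <- cbind(tab, eta)
  }
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path TSV path.
#' @return a `buv_draws` object.
#' @export
read_draws <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- function(tag) {
    ln <- hdr[startsWith(hdr, paste0("# ", tag))]
    lapply(strsplit(sub(paste0("^# ", tag, " "), "", ln), " "), identity)
  }
  spatial <- grepl("spatial=1", hdr[1])
  std <- as.numeric(meta("std")[[1]])
  pr <- as.numeric(meta("priors")[[1]])
  acc <- as.numeric(meta("accept_phi")[[1]])
  site_rows <- meta("site")
  sites <- data.frame(
    site_id = vapply(site_rows, `[`, "", 1),
    easting = as.numeric(vapply(site_rows, `[`, "", 2)),
    northing = as.numeric(vapply(site_rows, `[`, "", 3)),
    stringsAsFactors = FALSE)
  tab <- read.delim(textConnection(body), check.names = FALSE)
  beta_cols <- grep("^beta_", names(tab))
  beta <- as.matrix(tab[beta_cols])
  colnames(beta) <- DESIGN_COLUMNS[seq_along(beta_cols)]
  out <- list(beta = beta, spatial = spatial, sites = sites,
              std_params = structure(list(depth_mean = std[1],
                                          depth_sd = std[2],
                                          visibility_mean = std[3],
                                          visibility_sd = std[4]),
                                     class = "buv_standardization"),
              priors = prior_spec(pr[1], pr[2], pr[3], pr[4], pr[5]),
              config = fit_config(spatial = spatial,
                                  n_retained = nrow(beta)),
              term_names = colnames(beta),
              accept = c(beta = 1, eta = if (spatial) 1 else NA,
                         phi = acc))
  if (spatial) {
    eta_cols <- grep("^eta_", names(tab))
    eta <- as.matrix(tab[eta_cols])
    colnames(eta) <- sub("^eta_", "", names(tab)[eta_cols])
    out$eta <- eta
    out$sigma2 <- tab$sigma2
    out$phi <- tab$phi
  }
  structure(out, class = "buv_draws")
}
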