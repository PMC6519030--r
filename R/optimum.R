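#' Optimal laying date from the caterpillar biomass peak
#'
#' The laying date at which fitness is maximized: the peak date of
#' caterpillar biomass minus the rearing lag — the ~33 days from laying
#' through incubation to peak chick food demand.
#'
#' @param peak_date peak date(s), April-day scale.
#' @param offset rearing lag in days (default 33).
#' @return `peak_date - offset`.
#' @examples
#' optimal_laying_date(120) # 87
#' @export
optimal_laying_date <- function(peak_date, offset = 33) {
  stopifnot(all(is.finite(peak_date)))
  peak_date - offset
}

#' Define consecutive study periods
#'
#' @param breaks list of `c(first, last)` year pairs, or a character vector
#'   like `"1973-1987"`. Defaults to the three 14-15 year thirds of a
#'   1973-2016 study.
#' @return data.frame `label`, `first`, `last`; periods must be ordered and
#'   non-overlapping.
#' @export
period_definition <- function(breaks = c("1973-1987", "1988-2001", "2002-2016")) {
  if (is.character(breaks)) {
    parts <- strsplit(breaks, "-", fixed = TRUE)
    breaks <- lapply(parts, function(p) as.integer(p))
  }
  out <- data.frame(label = vapply(breaks, function(b) paste0(b[1], "-", b[2]), ""),
                    first = as.integer(vapply(breaks, `[`, 0, 1)),
                    last = as.integer(vapply(breaks, `[`, 0, 2)))
  stopifnot(all(out$first <= out$last))
  if (nrow(out) > 1 && any(out$first[-1] <= out$last[-nrow(out)]))
    stop("periods must be ordered and non-overlapping")
  out
}

assign_period <- function(year, periods) {
  p <- rep(NA_integer_, length(year))
  for (i in seq_len(nrow(periods)))
    p[year >= periods$first[i] & year <= periods$last[i]] <- i
  p
}

#' Hindcast missing caterpillar peak dates from the temperature cue
#'
#' Fills missing `peak_date` values by ordinary least squares of observed
#' peak dates on cue temperature over the calibration years; observed peaks
#' are untouched and `optimal_laying_date` is refreshed. A warning is
#' issued when a hindcast temperature falls outside the calibration range
#' (extrapolation).
#'
#' @param environments environment table with possibly missing `peak_date`.
#' @param calibration_years years whose observed peaks calibrate the
#'   regression (default: all years with an observed peak); at least 3.
#' @param offset rearing lag passed to [optimal_laying_date()].
#' @return the environment table with peaks filled and an attribute
#'   `hindcast_fit` = c(intercept, slope).
#' @export
hindcast_peaks <- function(environments,
                           calibration_years = environments$year[!is.na(environments$peak_date)],
                           offset = 33) {
  cal <- environments[environments$year %in% calibration_years &
                        !is.na(environments$peak_date), ]
  if (nrow(cal) < 3)
    stop("need at least 3 calibration years with observed peaks, got ", nrow(cal))
  fit <- stats::lm(peak_date ~ cue_temp, data = cal)
  fill <- which(is.na(environments$peak_date))
  if (length(fill)) {
    tt <- environments$cue_temp[fill]
    out_of_range <- tt < min(cal$cue_temp) | tt > max(cal$cue_temp)
    if (any(out_of_range))
      warning("hindcast temperature outside the calibration range for year(s) ",
              paste(environments$year[fill][out_of_range], collapse = ", "))
    environments$peak_date[fill] <- stats::predict(fit, data.frame(cue_temp = tt))
  }
  environments$optimal_laying_date <- optimal_laying_date(environments$peak_date, offset)
  attr(environments, "hindcast_fit") <- stats::coef(fit)
  environments
}

# statistic engine shared by point fit, bootstrap and jackknife:
# OLS of LDtheta on centred temperature with period indicators (and
# period x temperature when common_slope is off); elevations reported at
# the grand-mean temperature of the full (non-excluded) dataset.
optimum_stats <- function(tc, ld, per, n_per, common_slope) {
  if (common_slope) {
    X <- cbind(outer(per, seq_len(n_per), `==`) + 0, tc)
  } else {
    X <- cbind(outer(per, seq_len(n_per), `==`) + 0,
               outer(per, seq_len(n_per), `==`) * tc)
  }
  cf <- stats::coef(stats::lm.fit(X, ld))
  elev <- cf[seq_len(n_per)]
  slope <- if (common_slope) rep(cf[n_per + 1], n_per) else cf[(n_per + 1):(2 * n_per)]
  out <- c(elev, slope)
  if (n_per > 1) {
    out <- c(out, elev[-1] - elev[1], slope[-1] - slope[1])
  }
  out <- c(out, tapply(ld, per, function(v) if (length(v) > 1) stats::var(v) else 0)[
    as.character(seq_len(n_per))])
  out
}

optimum_stat_names <- function(labels, common_slope) {
  n <- length(labels)
  nm <- c(paste0("elevation_", labels), paste0("slope_", labels))
  if (n > 1)
    nm <- c(nm, paste0("elev_diff_", labels[-1], "_vs_", labels[1]),
            paste0("slope_diff_", labels[-1], "_vs_", labels[1]))
  c(nm, paste0("var_", labels))
}

#' Fit the optimal reaction norm by period
#'
#' Regresses the optimal laying date on the cue temperature with period
#' indicators — a common slope by default, or a period x temperature
#' interaction — and reports per-period elevations (at the grand-mean
#' temperature, so elevation changes are not contaminated by slope
#' differences), slopes, between-period differences and per-period
#' interannual variances, each with a BCa bootstrap confidence interval.
#' The bootstrap resamples years within periods (the optimum is a yearly
#' quantity); excluded years (e.g. frost-damage years) are dropped first.
#'
#' @param environments table with `year`, `cue_temp`, `optimal_laying_date`
#'   and logical `excluded`.
#' @param periods a [period_definition()] table.
#' @param common_slope single temperature slope across periods (default) or
#'   period-specific slopes.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level interval mass.
#' @param seed integer seed.
#' @return `rn_optimum_fit`: data.frame `estimates` (statistic, estimate,
#'   lower, upper), the excluded years, and settings.
#' @export
fit_optimum_by_period <- function(environments, periods = period_definition(),
                                  common_slope = TRUE, n_boot = 1000,
                                  level = 0.95, seed = 1L) {
  env <- environments[!environments$excluded &
                        !is.na(environments$optimal_laying_date), ]
  per <- assign_period(env$year, periods)
  keep <- !is.na(per)
  env <- env[keep, ]; per <- per[keep]
  n_per <- nrow(periods)
  if (any(tabulate(per, n_per) < 3))
    stop("each period needs at least 3 non-excluded years")
  if (any(tapply(env$cue_temp, per, stats::sd) == 0))
    stop("degenerate design: constant temperature within a period")

  tc <- env$cue_temp - mean(env$cue_temp)
  ld <- env$optimal_laying_date
  stat <- function(idx) optimum_stats(tc[idx], ld[idx], per[idx], n_per, common_slope)

  theta <- stat(seq_along(ld))
  set.seed(seed)
  idx_by_per <- split(seq_along(ld), per)
  boot <- t(replicate(n_boot, {
    idx <- unlist(lapply(idx_by_per, function(ix)
      ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
    stat(idx)
  }))
  jack <- t(vapply(seq_along(ld), function(i) stat(seq_along(ld)[-i]), theta))

  ci <- t(vapply(seq_along(theta), function(k)
    bca_interval(theta[k], boot[, k], jack[, k], level), numeric(2)))
  est <- data.frame(statistic = optimum_stat_names(periods$label, common_slope),
                    estimate = unname(theta), lower = ci[, 1], upper = ci[, 2])
  structure(list(estimates = est,
                 excluded_years = environments$year[environments$excluded],
                 periods = periods, common_slope = common_slope,
                 n_boot = n_boot, level = level, n_years = nrow(env)),
            class = "rn_optimum_fit")
}

#' @export
print.rn_optimum_fit <- function(x, ...) {
  cat("Optimal reaction norm over", nrow(x$periods), "periods (",
      x$n_years, "years;", x$n_boot, "BCa bootstrap iterations)\n")
  print(x$estimates, digits = 4, row.names = FALSE)
  if (length(x$excluded_years))
    cat("excluded years:", paste(x$excluded_years, collapse = ", "), "\n")
  invisible(x)
}

#' Interannual variance of the optimal laying date by period
#'
#' Unbiased sample variance of the yearly optimum within each period, with
#' BCa intervals over resampled years.
#'
#' @inheritParams fit_optimum_by_period
#' @return data.frame `period`, `n_years`, `variance`, `lower`, `upper`.
#' @export
optimum_variance_by_period <- function(environments, periods = period_definition(),
                                       n_boot = 1000, level = 0.95, seed = 1L) {
  env <- environments[!environments$excluded &
                        !is.na(environments$optimal_laying_date), ]
  per <- assign_period(env$year, periods)
  set.seed(seed)
  out <- lapply(seq_len(nrow(periods)), function(i) {
    ld <- env$optimal_laying_date[which(per == i)]
    if (length(ld) < 3) stop("period ", periods$label[i], " has fewer than 3 years")
    v <- stats::var(ld)
    boot <- replicate(n_boot, stats::var(sample(ld, replace = TRUE)))
    jack <- vapply(seq_along(ld), function(j) stats::var(ld[-j]), 0)
    ci <- bca_interval(v, boot, jack, level)
    data.frame(period = periods$label[i], n_years = length(ld),
               variance = v, lower = ci[1], upper = ci[2])
  })
  do.call(rbind, out)
}
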