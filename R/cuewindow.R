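#' Mean temperature over a day-of-year window
#'
#' Arithmetic mean of daily values across the inclusive window
#' `start_doy..end_doy` of one year. Errors (listing the gaps) when any day
#' of the window is missing.
#'
#' @param series data.frame with `year`, `doy`, `temperature` (as from
#'   [simulate_daily_temperatures()] or [read_daily_temperatures()]).
#' @param start_doy,end_doy inclusive window bounds (day of year).
#' @param year calendar year.
#' @return mean temperature, degrees C.
#' @export
window_mean <- function(series, start_doy, end_doy, year) {
  stopifnot(start_doy <= end_doy)
  s <- series[series$year == year & series$doy >= start_doy &
                series$doy <= end_doy, ]
  want <- seq(start_doy, end_doy)
  gaps <- setdiff(want, s$doy)
  if (length(gaps))
    stop("missing day(s) of year ", year, ": ",
         paste(utils::head(gaps, 10), collapse = ", "))
  mean(s$temperature)
}

#' Sliding-window search for the best temperature cue window
#'
#' Exhaustive grid search over candidate windows (inclusive day-of-year
#' start and end): for each window, the annual window means are correlated
#' with the annual response series, and the window maximizing the squared
#' Pearson correlation is returned. Ties are broken by earliest start,
#' then shortest window. This is a plain r-squared grid search — no
#' model-weighting or randomization — intended for data where the response
#' is driven by a single contiguous window.
#'
#' @param series daily temperature data.frame (`year`, `doy`,
#'   `temperature`) covering every candidate day for every response year.
#' @param annual_response data.frame `year`, `response` (>= 5 years).
#' @param start_range,end_range integer ranges (vectors whose range is
#'   used) of candidate start/end days of year.
#' @param min_length minimum window length in days (default 7).
#' @return list of class `rn_cue_window`: `start_doy`, `end_doy`,
#'   `r_squared`, `slope` (of response on window mean), and `grid`
#'   (data.frame of all windows with their r-squared).
#' @export
find_best_window <- function(series, annual_response,
                             start_range = c(32, 110), end_range = c(46, 130),
                             min_length = 7) {
  resp <- annual_response[is.finite(annual_response$response), ]
  if (nrow(resp) < 5) stop("need at least 5 years of response values")
  if (stats::sd(resp$response) == 0) stop("response constant")
  years <- resp$year

  starts <- seq(min(start_range), max(start_range))
  ends <- seq(min(end_range), max(end_range))
  grid <- expand.grid(start_doy = starts, end_doy = ends)
  grid <- grid[grid$end_doy - grid$start_doy + 1 >= min_length, ]
  if (!nrow(grid)) stop("empty candidate grid: min_length excludes all windows")

  # cumulative daily sums per year make each window mean O(1)
  doys <- seq(min(starts), max(ends))
  cums <- vapply(years, function(y) {
    s <- series[series$year == y & series$doy >= doys[1] &
                  series$doy <= doys[length(doys)], ]
    s <- s[order(s$doy), ]
    if (nrow(s) != length(doys) || any(s$doy != doys))
      stop("daily series does not cover days ", doys[1], "..",
           doys[length(doys)], " of year ", y)
    cumsum(s$temperature)
  }, numeric(length(doys)))

  wsum <- function(st, en) {
    hi <- cums[en - doys[1] + 1, ]
    lo <- if (st > doys[1]) cums[st - doys[1], ] else 0
    (hi - lo) / (en - st + 1)
  }
  r2 <- vapply(seq_len(nrow(grid)), function(k) {
    m <- wsum(grid$start_doy[k], grid$end_doy[k])
    if (stats::sd(m) == 0) return(0)
    stats::cor(m, resp$response)^2
  }, 0)
  grid$r_squared <- r2

  # argmax; ties -> earliest start, then shortest window
  best <- which(r2 >= max(r2) - 1e-12)
  best <- best[order(grid$start_doy[best],
                     grid$end_doy[best] - grid$start_doy[best])][1]
  m <- wsum(grid$start_doy[best], grid$end_doy[best])
  structure(list(start_doy = grid$start_doy[best],
                 end_doy = grid$end_doy[best],
                 r_squared = grid$r_squared[best],
                 slope = unname(stats::coef(stats::lm(resp$response ~ m))[2]),
                 grid = grid),
            class = "rn_cue_window")
}

#' @export
print.rn_cue_window <- function(x, ...) {
  cat("Best cue window: day", x$start_doy, "to", x$end_doy,
      sprintf("(r^2 = %.3f, slope = %.2f per degree C)\n", x$r_squared, x$slope))
  invisible(x)
}
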