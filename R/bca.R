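#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa: the bias-correction `z0` is the normal quantile of the
#' fraction of bootstrap replicates below the point estimate (ties counted
#' half), and the acceleration `a` is the jackknife skewness
#' `sum(d^3) / (6 sum(d^2)^{3/2})` with `d = mean(jack) - jack`. Adjusted
#' quantile levels are
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha)))`.
#' A degenerate bootstrap distribution (all replicates equal within machine
#' precision) returns a zero-width interval with a warning.
#'
#' @param point_estimate the statistic on the original sample.
#' @param bootstrap_replicates numeric vector of bootstrap statistics
#'   (at least 100; non-finite replicates are dropped).
#' @param jackknife_replicates leave-one-out statistics.
#' @param level interval mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
bca_interval <- function(point_estimate, bootstrap_replicates,
                         jackknife_replicates, level = 0.95) {
  boot <- bootstrap_replicates[is.finite(bootstrap_replicates)]
  if (length(boot) < 100)
    stop("need at least 100 finite bootstrap replicates, got ", length(boot))
  stopifnot(level > 0, level < 1, is.finite(point_estimate))

  rng <- range(boot)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[1]))) {
    warning("degenerate bootstrap distribution; zero-width interval")
    return(c(boot[1], boot[1]))
  }

  prop <- (sum(boot < point_estimate) + 0.5 * sum(boot == point_estimate)) /
    length(boot)
  prop <- min(max(prop, 1 / (2 * length(boot))), 1 - 1 / (2 * length(boot)))
  z0 <- stats::qnorm(prop)

  jack <- jackknife_replicates[is.finite(jackknife_replicates)]
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0

  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(stats::quantile(boot, adj, type = 6))
}
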