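#' Fit an annual fitness surface over laying date
#'
#' Penalized-spline regression of recruit counts on laying date with a log
#' link: negative binomial by default (dispersion estimated), with a
#' Poisson fallback when the negative-binomial fit fails or its dispersion
#' is unidentifiable. Smoothness is chosen by REML (default) or GCV.
#' Returns a callable expected-fitness surface and its derivative (exact
#' chain-rule derivative of the log-link linear predictor, evaluated by
#' finite differences of the spline basis).
#'
#' @param laying_dates,recruits numeric vectors, one entry per brood.
#' @param family `"nb"` or `"poisson"`.
#' @param smoothness_selection mgcv smoothing criterion (`"REML"`/`"GCV.Cp"`).
#' @param k spline basis dimension (kept small; annual samples are modest).
#' @return list of class `rn_fitness_surface`: `W(z)` expected fitness,
#'   `dW(z)` its derivative, the fitted `gam`, `family_used`, `theta`
#'   (NB dispersion or NA), and the data.
#' @export
fit_fitness_surface <- function(laying_dates, recruits,
                                family = c("nb", "poisson"),
                                smoothness_selection = "REML", k = 5) {
  family <- match.arg(family)
  stopifnot(length(laying_dates) == length(recruits),
            all(is.finite(laying_dates)), all(recruits >= 0))
  df <- data.frame(z = laying_dates, w = recruits)
  k <- min(k, max(3, length(unique(df$z)) - 1))

  fit <- NULL
  family_used <- family
  if (family == "nb") {
    fit <- tryCatch(
      mgcv::gam(w ~ s(z, k = k), family = mgcv::nb(),
                data = df, method = smoothness_selection),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && !fit$converged) fit <- NULL
    if (is.null(fit)) family_used <- "poisson"
  }
  if (is.null(fit)) {
    fit <- mgcv::gam(w ~ s(z, k = k), family = stats::poisson(),
                     data = df, method = smoothness_selection)
    family_used <- "poisson"
  }
  if (!fit$converged) stop("fitness-surface fit did not converge")

  theta <- if (family_used == "nb") fit$family$getTheta(TRUE) else NA_real_
  W <- function(z) as.numeric(stats::predict(fit, data.frame(z = z),
                                             type = "response"))
  dW <- function(z, h = 1e-3) {
    eta1 <- stats::predict(fit, data.frame(z = z + h), type = "link")
    eta0 <- stats::predict(fit, data.frame(z = z - h), type = "link")
    as.numeric(W(z) * (eta1 - eta0) / (2 * h)) # d/dz exp(eta) = exp(eta) eta'
  }
  structure(list(W = W, dW = dW, gam = fit, family_used = family_used,
                 theta = theta, z = df$z, w = df$w, k = k,
                 smoothness_selection = smoothness_selection),
            class = "rn_fitness_surface")
}

#' Directional selection gradient from a fitness surface
#'
#' Average-derivative Lande-Arnold gradient of relative fitness on the
#' unstandardized trait scale (per day of laying date):
#' `beta_z = mean(W'(z_i)) / mean(W(z_i))` over the observed laying dates.
#' The standard error comes from a parametric bootstrap: counts are redrawn
#' from the fitted family at the fitted means, the surface refitted, and
#' the gradient recomputed.
#'
#' @param surface an [fit_fitness_surface()] object, or a list with
#'   functions `W` and `dW` (an analytic surface; the bootstrap then
#'   requires a fitted object and is skipped with `se = NA`).
#' @param laying_dates trait values over which the derivative is averaged
#'   (defaults to the surface's own data).
#' @param n_boot parametric-bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return list `beta_z`, `se`, `n_boot_ok` (refits that converged).
#' @export
directional_gradient <- function(surface, laying_dates = surface$z,
                                 n_boot = 1000, seed = 1L) {
  wbar <- mean(surface$W(laying_dates))
  if (!is.finite(wbar) || wbar <= 0)
    stop("mean fitness is zero; relative-fitness gradient undefined")
  beta <- mean(surface$dW(laying_dates)) / wbar

  se <- NA_real_
  n_ok <- 0L
  if (!is.null(surface$gam) && n_boot > 0) {
    set.seed(seed)
    mu <- surface$W(surface$z)
    reps <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      wb <- if (surface$family_used == "nb") {
        stats::rnbinom(length(mu), size = surface$theta, mu = mu)
      } else {
        stats::rpois(length(mu), mu)
      }
      sb <- tryCatch(
        fit_fitness_surface(surface$z, wb, family = surface$family_used,
                            smoothness_selection = surface$smoothness_selection,
                            k = surface$k),
        error = function(e) NULL)
      reps[b] <- if (is.null(sb)) NA_real_ else {
        wb2 <- mean(sb$W(laying_dates))
        if (wb2 > 0) mean(sb$dW(laying_dates)) / wb2 else NA_real_
      }
    }
    ok <- is.finite(reps)
    n_ok <- sum(ok)
    if (n_ok >= 10) se <- stats::sd(reps[ok])
  }
  list(beta_z = beta, se = se, n_boot_ok = n_ok)
}

#' Annual selection gradients on laying date
#'
#' Per-year fitness-surface fit and directional gradient over unmanipulated
#' broods. Records with unknown female identity are included — they are a
#' potentially biased subset of very early or very late layers. Years with
#' too few broods, constant recruits, or failed fits are reported with a
#' flag rather than silently dropped.
#'
#' @param records breeding-record data.frame.
#' @param min_broods minimum unmanipulated broods per year (default 15).
#' @param family,n_boot,seed passed to the per-year fit/gradient.
#' @return data.frame of class `rn_gradients`: `year`, `beta_z`, `se`, `n`,
#'   fit diagnostics (`edf`, the fitted smooth's effective degrees of
#'   freedom; `theta`, the negative-binomial dispersion, NA under the
#'   Poisson fallback; `family`), and `flag` (`"ok"`, `"too_few_broods"`,
#'   `"constant_fitness"`, `"fit_failed"`).
#' @export
annual_gradients <- function(records, min_broods = 15, family = "nb",
                             n_boot = 1000, seed = 1L) {
  years <- sort(unique(records$year))
  out <- lapply(seq_along(years), function(i) {
    y <- years[i]
    rec <- records[records$year == y & !records$manipulated, ]
    row <- data.frame(year = y, beta_z = NA_real_, se = NA_real_,
                      n = nrow(rec), edf = NA_real_, theta = NA_real_,
                      family = NA_character_, flag = "ok",
                      stringsAsFactors = FALSE)
    if (nrow(rec) < min_broods) {
      row$flag <- "too_few_broods"
      return(row)
    }
    if (stats::var(rec$recruits) == 0) {
      # flat observed fitness: zero gradient by definition
      row$beta_z <- 0; row$se <- 0; row$flag <- "constant_fitness"
      return(row)
    }
    res <- tryCatch({
      surf <- fit_fitness_surface(rec$laying_date, rec$recruits, family = family)
      c(directional_gradient(surf, n_boot = n_boot, seed = seed + i),
        list(edf = sum(surf$gam$edf), theta = surf$theta,
             family = surf$family_used))
    }, error = function(e) NULL)
    if (is.null(res)) {
      row$flag <- "fit_failed"
    } else {
      row$beta_z <- res$beta_z; row$se <- res$se
      row$edf <- res$edf; row$theta <- res$theta; row$family <- res$family
    }
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("rn_gradients", "data.frame")
  out
}
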