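#' Map environment-specific gradients onto reaction-norm components
#'
#' Selection gradients on the reaction-norm intercept and slope are the
#' environment-weighted aggregate of the per-environment gradients:
#' `beta_g = Phi' beta_z` with the rows of `Phi` being `(1, x_i)` for the
#' (centred) environmental value of each environment.
#'
#' @param beta_z_by_env vector of per-environment selection gradients.
#' @param env_values matching vector of centred environmental values.
#' @return length-2 vector `(intercept, slope)` gradient.
#' @export
map_gradients_to_rn <- function(beta_z_by_env, env_values) {
  stopifnot(length(beta_z_by_env) == length(env_values))
  c(intercept = sum(beta_z_by_env), slope = sum(env_values * beta_z_by_env))
}

#' Single-year genetic response of the reaction norm
#'
#' The reaction-norm breeder's equation for one year:
#' `dg = G (1, x_j)' beta_zj`, optionally multiplied by the recruit
#' fraction of the next breeding population (generation-time correction)
#' and halved when the trait is sex-limited (expressed by females only).
#'
#' @param G 2x2 additive-genetic covariance matrix of intercept (day^2) and
#'   slope ((days/degree C)^2).
#' @param x_j centred environmental value of the selection year.
#' @param beta_zj selection gradient (per day).
#' @param p_recr_next recruit fraction of the year-(j+1) breeding
#'   population, in [0, 1] (default 1 = no correction).
#' @param sex_limited halve the response (default FALSE).
#' @return length-2 vector: change in intercept (days) and slope
#'   (days/degree C).
#' @export
annual_response <- function(G, x_j, beta_zj, p_recr_next = 1,
                            sex_limited = FALSE) {
  G <- as.matrix(G)
  stopifnot(nrow(G) == 2, ncol(G) == 2,
            p_recr_next >= 0, p_recr_next <= 1)
  if (G[1, 2] != G[2, 1] ||
      G[1, 1] < 0 || G[2, 2] < 0 ||
      G[1, 2]^2 > G[1, 1] * G[2, 2] + 1e-8)
    stop("G must be a symmetric PSD 2x2 matrix")
  dg <- as.numeric(G %*% c(1, x_j)) * beta_zj * p_recr_next *
    (if (sex_limited) 0.5 else 1)
  stats::setNames(dg, c("d_intercept", "d_slope"))
}

#' First-order standard error of the annual response
#'
#' Error propagation for the product `G (1, x_j)' beta_zj`: elementwise
#' `SE = sqrt( (G(1,x)')^2 V(beta) + beta^2 V(G(1,x)') )`, where the
#' variance of each component of `G (1, x)'` is assembled from the
#' component SEs of G (`V = V(G_i1) + x^2 V(G_i2)`). Component SEs of G are
#' conventionally derived from 95% HPDIs as (half the interval width)/1.96,
#' a normal approximation that is conservative for zero-bounded, skewed
#' variance posteriors. The result is scaled by the same
#' `p_recr * 0.5` factors as the point estimate.
#'
#' @inheritParams annual_response
#' @param se_beta standard error of `beta_zj`.
#' @param se_G 2x2 matrix of component standard errors of G.
#' @return length-2 vector of SEs.
#' @export
propagate_se <- function(G, x_j, beta_zj, se_beta, se_G,
                         p_recr_next = 1, sex_limited = FALSE) {
  G <- as.matrix(G); se_G <- as.matrix(se_G)
  stopifnot(all(se_G >= 0), se_beta >= 0)
  gvec <- as.numeric(G %*% c(1, x_j))
  v_gvec <- c(se_G[1, 1]^2 + x_j^2 * se_G[1, 2]^2,
              se_G[2, 1]^2 + x_j^2 * se_G[2, 2]^2)
  se <- sqrt(gvec^2 * se_beta^2 + beta_zj^2 * v_gvec)
  se <- se * p_recr_next * (if (sex_limited) 0.5 else 1)
  stats::setNames(se, c("d_intercept", "d_slope"))
}

#' Cumulative response with a propagated confidence interval
#'
#' Component-wise sums of the per-year responses; the CI half-width is
#' `1.96 * sqrt(sum(SE^2))` (independent-error approximation), symmetric
#' about the cumulative point estimate.
#'
#' @param d_int,d_slope per-year responses.
#' @param se_int,se_slope per-year SEs.
#' @return list `cum` (2-vector), `se` (2-vector), `lower`, `upper`.
#' @export
cumulative_response <- function(d_int, d_slope, se_int, se_slope) {
  ok <- is.finite(d_int) & is.finite(d_slope)
  cum <- c(d_intercept = sum(d_int[ok]), d_slope = sum(d_slope[ok]))
  se <- c(d_intercept = sqrt(sum(se_int[ok]^2)),
          d_slope = sqrt(sum(se_slope[ok]^2)))
  list(cum = cum, se = se, lower = cum - 1.96 * se, upper = cum + 1.96 * se)
}

#' G-matrix point estimates and SEs from a fitted RRAM
#'
#' Extracts the posterior-median 2x2 G (and permanent-environment) matrix
#' and HPDI-derived component SEs from an [fit_model()] `"rram"` fit.
#'
#' @param fit an `rn_fit` from the rram.
#' @return list `G`, `se_G`, `grand_mean_temp`.
#' @export
extract_G <- function(fit) {
  stopifnot(inherits(fit, "rn_fit"), fit$spec$type == "rram", fit$spec$additive)
  s <- fit$summary
  pick <- function(p, col) s[[col]][match(p, s$parameter)]
  G <- matrix(c(pick("V_a_int", "median"), pick("cov_a", "median"),
                pick("cov_a", "median"), pick("V_a_slope", "median")), 2)
  se_G <- matrix(c(pick("V_a_int", "upper") - pick("V_a_int", "lower"),
                   pick("cov_a", "upper") - pick("cov_a", "lower"),
                   pick("cov_a", "upper") - pick("cov_a", "lower"),
                   pick("V_a_slope", "upper") - pick("V_a_slope", "lower")),
                 2) / (2 * 1.96)
  list(G = G, se_G = se_G, grand_mean_temp = fit$grand_mean_temp)
}

#' Predict the evolutionary trajectory of the reaction norm
#'
#' Applies the reaction-norm breeder's equation year by year after a
#' baseline period: each post-baseline year contributes
#' `G (1, x_j)' beta_zj * p_recr(j+1) * 0.5` (the halving because the trait
#' is expressed by females only), with first-order SEs, and the cumulative
#' change accumulates across years with a `1.96 sqrt(sum SE^2)` interval.
#' The uncorrected mode drops the recruit-fraction and sex-limitation
#' factors, giving the pure multivariate-breeder's-equation upper bound.
#'
#' Environmental values are centred with the grand-mean temperature stored
#' in the G source so predictions are centring-consistent with the fit.
#'
#' @param G,se_G 2x2 matrices (e.g. from [extract_G()]).
#' @param gradients data.frame `year`, `beta_z`, `se` (as from
#'   [annual_gradients()]; rows with NA gradient are skipped with a flag).
#' @param environments table with `year`, `cue_temp`.
#' @param p_recr data.frame `year`, `p_recr` (see [p_recr_by_year()]);
#'   ignored in uncorrected mode.
#' @param baseline_period `c(first, last)` years establishing the initial
#'   reaction norm; prediction starts after `last`.
#' @param grand_mean_temp centring constant (default: mean cue temperature
#'   across all years supplied).
#' @param corrected apply the recruit-fraction and sex-limitation factors
#'   (default TRUE).
#' @return `rn_trajectory`: `by_year` data.frame (year, x_j, beta_z, se,
#'   p_recr_next, d_int, d_slope, se_int, se_slope, flag) and `cumulative`
#'   (from [cumulative_response()]).
#' @export
predict_trajectory <- function(G, se_G, gradients, environments, p_recr,
                               baseline_period,
                               grand_mean_temp = mean(environments$cue_temp),
                               corrected = TRUE) {
  years <- sort(environments$year[environments$year > baseline_period[2]])
  if (!length(years)) stop("baseline period covers all years; nothing to predict")
  rows <- lapply(years, function(y) {
    x <- environments$cue_temp[environments$year == y] - grand_mean_temp
    gi <- match(y, gradients$year)
    b <- if (is.na(gi)) NA_real_ else gradients$beta_z[gi]
    sb <- if (is.na(gi)) NA_real_ else gradients$se[gi]
    pr <- if (corrected) {
      pi <- match(y + 1, p_recr$year)
      if (is.na(pi)) NA_real_ else p_recr$p_recr[pi]
    } else 1
    flag <- if (is.na(b)) "no_gradient" else if (is.na(pr)) "no_p_recr" else "ok"
    if (flag != "ok") {
      return(data.frame(year = y, x_j = x, beta_z = b, se = sb,
                        p_recr_next = pr, d_int = NA_real_, d_slope = NA_real_,
                        se_int = NA_real_, se_slope = NA_real_, flag = flag))
    }
    dg <- annual_response(G, x, b, pr, sex_limited = corrected)
    se <- propagate_se(G, x, b, if (is.finite(sb)) sb else 0, se_G, pr,
                       sex_limited = corrected)
    data.frame(year = y, x_j = x, beta_z = b, se = sb, p_recr_next = pr,
               d_int = dg[1], d_slope = dg[2],
               se_int = se[1], se_slope = se[2], flag = "ok")
  })
  by_year <- do.call(rbind, rows)
  cum <- cumulative_response(by_year$d_int, by_year$d_slope,
                             by_year$se_int, by_year$se_slope)
  structure(list(by_year = by_year, cumulative = cum,
                 corrected = corrected, baseline_period = baseline_period,
                 grand_mean_temp = grand_mean_temp),
            class = "rn_trajectory")
}

#' @export
print.rn_trajectory <- function(x, ...) {
  n_ok <- sum(x$by_year$flag == "ok")
  cat("Predicted reaction-norm evolution over", n_ok, "years",
      if (x$corrected) "(generation-time and sex-limitation corrected)\n"
      else "(uncorrected breeder's equation)\n")
  cat(sprintf("  cumulative elevation change: %.3f days [%.3f, %.3f]\n",
              x$cumulative$cum[1], x$cumulative$lower[1], x$cumulative$upper[1]))
  cat(sprintf("  cumulative slope change:     %.4f days/C [%.4f, %.4f]\n",
              x$cumulative$cum[2], x$cumulative$lower[2], x$cumulative$upper[2]))
  invisible(x)
}
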