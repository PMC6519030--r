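#' Simulation configuration for synthetic breeding data
#'
#' Builds and validates the parameter set that drives the synthetic-data
#' generator: a pedigreed population of females breeding once per year, whose
#' laying dates follow a linear reaction norm against a spring temperature
#' cue, with intercept--slope (co)variation partitioned into additive-genetic
#' and permanent-environment parts, year and nest-box effects, residual
#' variance that may increase with temperature, and recruit counts under
#' Gaussian stabilizing selection around a moving optimal laying date.
#'
#' Laying dates are on the April-day scale throughout: days since March 31,
#' so April 1 = day 1 and an intercept of 21.8 means late April.
#'
#' Defaults emulate a ~44-year study of ~3,000 females and ~4,900 broods.
#' Variance components default to the posterior medians of a random-regression
#' animal model of laying date in a long-term great tit population
#' (additive intercept variance 4.38 day^2, additive slope variance
#' 0.02 (days/degree C)^2, permanent-environment 3.24/0.02, year 9.65,
#' nest box 1.22, and four temperature-ordered residual variances
#' 11.09, 13.63, 19.21, 19.27 day^2), and the caterpillar-peak regression
#' defaults to a slope of -3.15 days/degree C with the 33-day lag between
#' laying and peak chick food demand.
#'
#' @param ... named overrides of any default listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{n_founders}{breeding females per year (the population is kept at
#'     this capacity); an equally sized male pool is simulated for the
#'     pedigree.}
#'   \item{n_years, year_start}{length and first calendar year of the study.}
#'   \item{mean_cue_temp, sd_cue_temp, temp_trend}{annual cue-window
#'     temperature: Normal(mean + trend * (year - year_start), sd), degrees C.}
#'   \item{peak_intercept, peak_slope, peak_resid_sd}{caterpillar peak date
#'     (April days) as a linear function of cue temperature plus noise.}
#'   \item{optimum_offset}{days between laying and peak chick food demand;
#'     optimal laying date = peak date - offset (default 33).}
#'   \item{sigma2_A, sigma2_B, cov_AB}{additive-genetic (co)variances of
#'     reaction-norm intercept (day^2) and slope ((days/degree C)^2).}
#'   \item{sigma2_PE_int, sigma2_PE_slope, cov_PE}{permanent-environment
#'     analogues.}
#'   \item{sigma2_year, sigma2_nestbox}{year and nest-box intercept variances.}
#'   \item{residual_sd_by_group}{residual standard deviations (days), ordered
#'     coldest to warmest temperature group of years.}
#'   \item{resid_temp_dependence}{if FALSE, the first residual sd applies to
#'     all years.}
#'   \item{mean_laying_date, pop_slope}{fixed-effect intercept (older female
#'     at the grand-mean temperature) and population-level plasticity slope.}
#'   \item{age_young_effect, age_unknown_effect}{fixed laying-date offsets for
#'     first-year and unknown-age females.}
#'   \item{n_nestbox}{number of nest boxes (boxes are in excess of pairs).}
#'   \item{fitness_width, fitness_max}{width (days) and height (expected
#'     recruits at the optimum) of the Gaussian stabilizing fitness surface.}
#'   \item{overdispersion}{negative-binomial size parameter for realized
#'     recruit counts.}
#'   \item{recruitment_rate}{probability a breeding vacancy is filled by a
#'     locally born yearling rather than an immigrant.}
#'   \item{adult_survival}{annual survival probability of a breeder.}
#'   \item{unknown_id_frac}{fraction of breeding records whose female
#'     identity is blanked, biased towards extreme laying dates.}
#'   \item{manipulated_frac, manipulated_fitness_factor}{fraction of broods
#'     flagged as experimentally manipulated and the multiplicative effect of
#'     manipulation on expected recruits.}
#'   \item{seed}{integer seed used by [simulate_dataset()].}
#' }
#'
#' @return an object of class `rn_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_founders = 30, n_years = 10)
#' cfg$peak_slope
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_founders = 110L,
    n_years = 44L,
    year_start = 1973L,
    mean_cue_temp = 8.0,
    sd_cue_temp = 1.0,
    temp_trend = 0.035,
    peak_intercept = 78.0,
    peak_slope = -3.15,
    peak_resid_sd = 4.0,
    optimum_offset = 33,
    sigma2_A = 4.38,
    sigma2_B = 0.02,
    cov_AB = 0.07,
    sigma2_PE_int = 3.24,
    sigma2_PE_slope = 0.02,
    cov_PE = 0.06,
    sigma2_year = 9.65,
    sigma2_nestbox = 1.22,
    residual_sd_by_group = sqrt(c(11.09, 13.63, 19.21, 19.27)),
    resid_temp_dependence = TRUE,
    mean_laying_date = 21.8,
    pop_slope = -3.28,
    age_young_effect = 1.78,
    age_unknown_effect = 1.27,
    n_nestbox = 200L,
    fitness_width = 10,
    fitness_max = 0.9,
    overdispersion = 1.5,
    recruitment_rate = 0.55,
    adult_survival = 0.375,
    unknown_id_frac = 0.07,
    manipulated_frac = 0.25,
    manipulated_fitness_factor = 0.9,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "rn_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_founders >= 1, cfg$n_years >= 2,
    cfg$sd_cue_temp >= 0, cfg$peak_resid_sd >= 0,
    cfg$sigma2_A >= 0, cfg$sigma2_B >= 0,
    cfg$sigma2_PE_int >= 0, cfg$sigma2_PE_slope >= 0,
    cfg$sigma2_year >= 0, cfg$sigma2_nestbox >= 0,
    length(cfg$residual_sd_by_group) >= 1,
    all(cfg$residual_sd_by_group >= 0),
    cfg$fitness_width > 0, cfg$fitness_max >= 0,
    cfg$overdispersion > 0,
    cfg$recruitment_rate >= 0, cfg$recruitment_rate <= 1,
    cfg$adult_survival >= 0, cfg$adult_survival <= 1,
    cfg$unknown_id_frac >= 0, cfg$unknown_id_frac < 1,
    cfg$manipulated_frac >= 0, cfg$manipulated_frac < 1
  )
  # intercept-slope covariance matrices must be PSD
  if (cfg$cov_AB^2 > cfg$sigma2_A * cfg$sigma2_B + 1e-12)
    stop("additive (co)variance matrix is not positive semi-definite")
  if (cfg$cov_PE^2 > cfg$sigma2_PE_int * cfg$sigma2_PE_slope + 1e-12)
    stop("permanent-environment (co)variance matrix is not positive semi-definite")
  invisible(cfg)
}

#' @export
print.rn_config <- function(x, ...) {
  cat("Reaction-norm simulation config:", x$n_founders, "females/year,",
      x$n_years, "years from", x$year_start, "\n")
  cat("  G = [", x$sigma2_A, x$cov_AB, ";", x$cov_AB, x$sigma2_B, "]",
      " PE = [", x$sigma2_PE_int, x$cov_PE, ";", x$cov_PE, x$sigma2_PE_slope, "]\n")
  cat("  residual sd by temperature group:",
      paste(round(x$residual_sd_by_group, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a simulation config as YAML
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @param config an `rn_config` object.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
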