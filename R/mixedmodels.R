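#' Within-individual centring of temperature
#'
#' Splits each record's temperature into a within-individual component
#' `T_ij - Tbar_i` and a between-individual component `Tbar_i` (the
#' individual's mean across her records). The within component sums to zero
#' per individual; the two components reconstruct the original temperature
#' exactly. Separating them keeps a between-individual association between
#' temperature and phenotype (from individuals observed only in warm or only
#' in cold years) out of the plasticity slope.
#'
#' @param temperature numeric vector of temperatures, one per record.
#' @param individual individual id per record (NA allowed; such records get
#'   `within = 0` and `between = temperature`).
#' @return data.frame `within`, `between`.
#' @export
center_within_individual <- function(temperature, individual) {
  stopifnot(length(temperature) == length(individual),
            all(is.finite(temperature)))
  between <- temperature
  known <- !is.na(individual)
  if (any(known)) {
    m <- tapply(temperature[known], individual[known], mean)
    between[known] <- m[as.character(individual[known])]
  }
  data.frame(within = temperature - between, between = between)
}

#' Assign years to equal-count temperature groups
#'
#' Years are ranked by cue temperature (ties broken by year) and split into
#' `n_groups` contiguous blocks of as-equal-as-possible size, coldest block
#' first. Rank-based equal-count grouping (rather than equal temperature
#' width) guarantees every group holds years and its residual variance is
#' estimable. The conventional group count for a long study is the number
#' of years divided by ten, rounded.
#'
#' @param environments data.frame with `year` and `cue_temp`.
#' @param n_groups number of groups; default `max(1, round(n_years / 10))`.
#' @return named integer vector: group (1 = coldest) by year.
#' @examples
#' env <- data.frame(year = 2001:2004, cue_temp = c(3, 5, 7, 9))
#' assign_residual_groups(env, 2)
#' @export
assign_residual_groups <- function(environments,
                                   n_groups = max(1L, round(nrow(environments) / 10))) {
  stopifnot(n_groups >= 1, n_groups <= nrow(environments))
  year_temp_groups(environments, n_groups)
}

#' Contribution of slope variance to expected-value variance
#'
#' The variance in environment-specific expected trait values attributable
#' to among-individual variance in reaction-norm slopes: the slope variance
#' multiplied by the variance of the centred environmental values. Puts a
#' slope variance in (days/degree C)^2 on the same day^2 scale as the
#' intercept variance.
#'
#' @param sigma2_slope slope variance (scalar or chain).
#' @param centred_temps centred temperatures over the fitting window.
#' @return day^2 value(s).
#' @export
slope_variance_contribution <- function(sigma2_slope, centred_temps) {
  stopifnot(all(is.finite(sigma2_slope)), all(is.finite(centred_temps)))
  sigma2_slope * stats::var(centred_temps)
}

#' Model specification for the reaction-norm mixed models
#'
#' @param type `"rram"` for the univariate random-regression (animal) model
#'   of laying date on grand-mean-centred temperature, or `"bivariate"` for
#'   the laying-date + lifetime-reproductive-success selection model with
#'   within-individual centred temperature.
#' @param individual_slope random individual slopes (I x E) on top of random
#'   intercepts.
#' @param additive include the additive-genetic term via the pedigree
#'   (rram only).
#' @param centring `"grand-mean"` or `"within-individual"`; the bivariate
#'   model requires within-individual centring (the between-individual mean
#'   temperature then enters the fixed part).
#' @param n_resid_groups residual-variance groups of years along the
#'   temperature gradient; `NULL` = round(n_years/10) for rram, 2 for the
#'   bivariate model.
#' @param year_effect,nestbox_effect random year and nest-box intercepts.
#' @param lrs_resid_var fixed residual variance of the Poisson LRS trait
#'   (default 0.01; exactly zero does not mix).
#' @param min_records minimum breeding records per female (2 for the
#'   bivariate selection model, 1 otherwise).
#' @return an `rn_model_spec` list.
#' @export
model_spec <- function(type = c("rram", "bivariate"),
                       individual_slope = TRUE,
                       additive = (type == "rram"),
                       centring = if (type == "bivariate") "within-individual" else "grand-mean",
                       n_resid_groups = NULL,
                       year_effect = TRUE, nestbox_effect = TRUE,
                       lrs_resid_var = 0.01,
                       min_records = if (type == "bivariate") 2L else 1L) {
  type <- match.arg(type)
  centring <- match.arg(centring, c("grand-mean", "within-individual"))
  if (type == "bivariate" && centring != "within-individual")
    stop("the bivariate selection model requires within-individual centring")
  if (type == "bivariate" && additive)
    stop("additive structure is only supported in the rram")
  structure(list(type = type, individual_slope = individual_slope,
                 additive = additive, centring = centring,
                 n_resid_groups = n_resid_groups,
                 year_effect = year_effect, nestbox_effect = nestbox_effect,
                 lrs_resid_var = lrs_resid_var,
                 min_records = as.integer(min_records)),
            class = "rn_model_spec")
}

default_prior <- function(px = TRUE) {
  if (px) {
    # parameter-expanded prior: IW(nu = d, V = diag(d)) on the working
    # covariance with N(0, 25^2) working scales
    list(nu_pe = 2, V_pe = diag(2),
         nu_g = 2, V_g = diag(2),
         nu_fem = 3, V_fem = diag(3),
         a_scalar = 1e-3, b_scalar = 1e-3, alpha_V = 25^2)
  } else {
    list(nu_pe = 0.002, V_pe = diag(2) * 1e-4,
         nu_g = 0.002, V_g = diag(2) * 1e-4,
         nu_fem = 0.002, V_fem = diag(3) * 1e-4,
         a_scalar = 1e-3, b_scalar = 1e-3, alpha_V = 25^2)
  }
}

#' MCMC settings
#'
#' @param n_iter total iterations; @param burn burn-in; @param thin thinning.
#' @export
mcmc_settings <- function(n_iter = 6000L, burn = 1000L, thin = 5L) {
  stopifnot(n_iter > burn, thin >= 1)
  list(n_iter = as.integer(n_iter), burn = as.integer(burn),
       thin = as.integer(thin))
}

# build fixed-effect design shared by both models.
# Reference age class is "older" (effects are offsets of first-year and
# unknown-age females); temperature enters per the centring mode.
build_design <- function(records, environments, spec) {
  rec <- records[!is.na(records$female_id), , drop = FALSE]
  cnt <- table(rec$female_id)
  keep <- names(cnt)[cnt >= spec$min_records]
  rec <- rec[rec$female_id %in% keep, , drop = FALSE]
  if (!nrow(rec)) stop("no records left after the min-records filter")

  env <- environments[match(sort(unique(rec$year)), environments$year), ]
  if (anyNA(env$cue_temp)) stop("missing environment rows for some record years")
  temp <- env$cue_temp[match(rec$year, env$year)]

  X <- cbind(`(Intercept)` = 1,
             age_first_year = as.numeric(rec$age_class == "first-year"),
             age_unknown = as.numeric(rec$age_class == "unknown"))
  if (all(X[, "age_unknown"] == 0)) X <- X[, colnames(X) != "age_unknown"]

  grand_mean <- mean(env$cue_temp)
  if (spec$centring == "grand-mean") {
    tc <- temp - grand_mean
    if (stats::sd(tc) > 0) X <- cbind(X, temp_c = tc)
  } else {
    cw <- center_within_individual(temp, rec$female_id)
    tc <- cw$within
    X <- cbind(X, temp_within = tc, temp_between = cw$between - grand_mean)
    X <- X[, apply(X, 2, stats::sd) > 0 | colnames(X) == "(Intercept)",
           drop = FALSE]
  }

  fem_levels <- sort(unique(rec$female_id))
  ngrp <- spec$n_resid_groups
  if (is.null(ngrp))
    ngrp <- if (spec$type == "bivariate") 2L else max(1L, round(nrow(env) / 10))
  grp_by_year <- assign_residual_groups(env, ngrp)
  rg <- grp_by_year[as.character(rec$year)]

  list(rec = rec, X = X, tc = tc,
       fem = match(rec$female_id, fem_levels) - 1L,
       fem_levels = fem_levels,
       rg = as.integer(rg) - 1L, n_rg = as.integer(ngrp),
       yr = if (spec$year_effect) match(rec$year, env$year) - 1L else integer(nrow(rec)),
       n_yr = if (spec$year_effect) nrow(env) else 0L,
       nb = if (spec$nestbox_effect) as.integer(factor(rec$nestbox)) - 1L else integer(nrow(rec)),
       n_nb = if (spec$nestbox_effect) length(unique(rec$nestbox)) else 0L,
       grand_mean = grand_mean,
       resid_group_by_year = grp_by_year)
}

#' Fit a reaction-norm mixed model by Gibbs sampling
#'
#' Dispatches on the spec type. `"rram"`: univariate Gaussian
#' random-regression animal model of laying date with individual
#' (permanent-environment) and additive-genetic intercepts and slopes on
#' grand-mean-centred temperature, year and nest-box intercepts, and
#' heterogeneous residual variance across temperature groups of years.
#' `"bivariate"`: laying date (Gaussian, within-individual centred
#' temperature, between-individual mean temperature as a fixed effect) and
#' lifetime reproductive success (overdispersed Poisson with a small fixed
#' residual variance), with a 3x3 unstructured covariance matrix across the
#' female's laying-date intercept, slope, and LRS intercept.
#'
#' Records with unknown female identity are excluded (they cannot inform
#' individual effects); the bivariate model additionally keeps only females
#' with at least `min_records` (default 2) breeding attempts.
#'
#' @param records breeding-record data.frame (see [simulate_breeding_data()]
#'   or [read_breeding_table()]); for the bivariate model, per-female LRS is
#'   the sum of `recruits` across her records.
#' @param environments environment table covering the record years.
#' @param spec an [model_spec()] object.
#' @param pedigree pedigree data.frame; required iff `spec$additive`.
#' @param mcmc an [mcmc_settings()] list.
#' @param prior prior list (NULL = defaults for the chosen `px` mode).
#'   Covariance blocks get inverse-Wishart priors — `IW(nu = d, V = diag(d))`
#'   on the working covariance under parameter expansion, near-flat
#'   `IW(0.002, 1e-4 diag)` otherwise; scalar variances
#'   inverse-gamma(1e-3, 1e-3).
#' @param px parameter expansion (default TRUE): random-regression effects
#'   are scaled by working parameters with N(0, 25^2) priors, which keeps
#'   variance chains mobile near zero; reported (co)variances fold the
#'   scales back in. Disabled automatically when `fix_pe_cov` is given.
#' @param seed integer seed.
#' @param fix_resid optional vector of fixed residual variances (one per
#'   group), used e.g. in conjugate closed-form checks.
#' @param fix_pe_cov optional fixed individual covariance matrix.
#' @return an `rn_fit` object: `samples` (matrix of thinned draws, named
#'   columns), `summary` (per-parameter posterior median, 95% HPDI, ESS),
#'   plus the spec, centring constant, residual grouping, and settings.
#' @export
fit_model <- function(records, environments, spec = model_spec("rram"),
                      pedigree = NULL, mcmc = mcmc_settings(),
                      prior = NULL, seed = 1L, px = TRUE,
                      fix_resid = NULL, fix_pe_cov = NULL) {
  stopifnot(inherits(spec, "rn_model_spec"))
  if (spec$additive && is.null(pedigree))
    stop("additive structure requested but no pedigree supplied")
  if (!is.null(fix_pe_cov)) px <- FALSE
  if (is.null(prior)) prior <- default_prior(px)
  set.seed(seed)
  d <- build_design(records, environments, spec)
  if (!spec$individual_slope && nrow(prior$V_pe) == 2) {
    prior$V_pe <- prior$V_pe[1, 1, drop = FALSE]
    if (px) prior$nu_pe <- 1
  }

  control <- c(mcmc, list(fix_resid = fix_resid, fix_pe_cov = fix_pe_cov,
                          px = px))

  if (spec$type == "rram") {
    if (spec$additive) {
      rel <- build_relationship_inverse(pedigree)
      fem2ind <- match(d$fem_levels, rel$ids) - 1L
      if (anyNA(fem2ind))
        stop("females missing from the pedigree: ",
             paste(utils::head(d$fem_levels[is.na(fem2ind)], 5), collapse = ", "))
      Ainv <- rel$Ainv
    } else {
      Ainv <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(0, 0))
      fem2ind <- integer(0)
    }
    out <- rram_gibbs(d$rec$laying_date, d$X, d$fem, d$tc, d$rg, d$yr, d$nb,
                      length(d$fem_levels), d$n_yr, d$n_nb, d$n_rg,
                      spec$individual_slope, Ainv, fem2ind, prior, control)
    cn <- c(colnames(d$X),
            if (spec$individual_slope) c("V_pe_int", "cov_pe", "V_pe_slope")
            else "V_pe_int",
            if (spec$additive) c("V_a_int", "cov_a", "V_a_slope"),
            if (d$n_yr > 0) "V_year",
            if (d$n_nb > 0) "V_nestbox",
            paste0("V_resid_g", seq_len(d$n_rg)))
  } else {
    lrs <- tapply(d$rec$recruits, factor(d$rec$female_id, levels = d$fem_levels),
                  sum)
    out <- bivrrm_gibbs(d$rec$laying_date, d$X, d$fem, d$tc, d$rg, d$yr, d$nb,
                        length(d$fem_levels), d$n_yr, d$n_nb, d$n_rg,
                        as.numeric(lrs), spec$lrs_resid_var, prior, control)
    cn <- c(colnames(d$X), "lrs_intercept",
            "V_ld_int", "cov_int_slope", "V_ld_slope",
            "cov_int_lrs", "cov_slope_lrs", "V_lrs",
            if (d$n_yr > 0) "V_year",
            if (d$n_nb > 0) "V_nestbox",
            paste0("V_resid_g", seq_len(d$n_rg)))
  }

  samples <- out$samples
  colnames(samples) <- cn
  summ <- do.call(rbind, lapply(cn, function(nm)
    as.data.frame(posterior_summary(samples[, nm]))))
  summ <- cbind(parameter = cn, summ)
  rownames(summ) <- NULL

  structure(list(samples = samples, summary = summ, spec = spec,
                 grand_mean_temp = d$grand_mean,
                 resid_group_by_year = d$resid_group_by_year,
                 centred_temps = d$tc,
                 n_females = length(d$fem_levels), n_records = nrow(d$rec),
                 n_jitter = out$n_jitter, mcmc = mcmc, seed = seed),
            class = "rn_fit")
}

#' @export
print.rn_fit <- function(x, ...) {
  cat("Reaction-norm mixed model (", x$spec$type, "), ",
      x$n_records, " records / ", x$n_females, " females\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fit the random-regression animal model
#'
#' Convenience wrapper: [fit_model()] with a `"rram"` spec.
#' @inheritParams fit_model
#' @param ... passed to [model_spec()].
#' @export
fit_rram <- function(records, environments, pedigree,
                     mcmc = mcmc_settings(), seed = 1L, ...) {
  fit_model(records, environments, model_spec("rram", ...),
            pedigree = pedigree, mcmc = mcmc, seed = seed)
}

#' Fit the bivariate selection model for one cohort period
#'
#' Convenience wrapper: [fit_model()] with a `"bivariate"` spec on females
#' with at least two breeding attempts.
#' @inheritParams fit_model
#' @param ... passed to [model_spec()].
#' @export
fit_selection_rrm <- function(records, environments,
                              mcmc = mcmc_settings(), seed = 1L, ...) {
  fit_model(records, environments, model_spec("bivariate", ...),
            mcmc = mcmc, seed = seed)
}

#' Posterior summary of a chain
#'
#' Median, highest-posterior-density interval (the shortest interval
#' containing the requested mass) and effective sample size from the
#' initial-positive-sequence autocorrelation estimator. Medians are the
#' point summary because variance chains bounded at zero are right-skewed.
#'
#' @param chain numeric vector of (thinned) posterior draws.
#' @param level interval mass (default 0.95).
#' @return list `median`, `lower`, `upper`, `ess`.
#' @export
posterior_summary <- function(chain, level = 0.95) {
  stopifnot(length(chain) >= 100, level > 0, level < 1)
  h <- hpdi(chain, level)
  list(median = stats::median(chain), lower = h[1], upper = h[2],
       ess = ess(chain))
}

#' Highest posterior density interval
#'
#' @inheritParams posterior_summary
#' @return numeric `c(lower, upper)`; zero-width for a constant chain.
#' @export
hpdi <- function(chain, level = 0.95) {
  x <- sort(chain)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Effective sample size
#'
#' `n / (1 + 2 sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive estimate (Geyer's initial positive sequence, applied
#' to single lags).
#'
#' @param chain numeric vector.
#' @return effective sample size (capped at the chain length; NA for a
#'   constant chain).
#' @export
ess <- function(chain) {
  n <- length(chain)
  if (stats::var(chain) == 0) return(NA_real_)
  ac <- stats::acf(chain, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (rho in ac) {
    if (rho <= 0) break
    s <- s + rho
  }
  min(n, n / (1 + 2 * s))
}
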