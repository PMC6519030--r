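#' Decide whether a fit detects individual slope variance
#'
#' Default criterion: the posterior probability that the slope-variance
#' contribution to expected-value variance (slope variance times the
#' variance of centred temperatures) exceeds a practical threshold —
#' a configurable fraction (default 5%) of the total individual variance —
#' is above `prob` (default 0.90). The `"hpdi"` alternative flags detection
#' when the HPDI lower bound of the slope variance clears a small floor.
#'
#' @param fit an `rn_fit` with a `V_pe_slope` chain.
#' @param criterion `"contribution"` (default) or `"hpdi"`.
#' @param threshold fraction of total individual variance
#'   (`"contribution"`) or absolute floor (`"hpdi"`).
#' @param prob posterior-probability cutoff for `"contribution"`.
#' @return logical.
#' @export
detect_slope_variance <- function(fit, criterion = c("contribution", "hpdi"),
                                  threshold = 0.05, prob = 0.90) {
  criterion <- match.arg(criterion)
  s <- fit$samples
  if (!"V_pe_slope" %in% colnames(s)) stop("fit has no slope-variance chain")
  vs <- s[, "V_pe_slope"]
  if (criterion == "contribution") {
    contrib <- slope_variance_contribution(vs, fit$centred_temps)
    total <- s[, "V_pe_int"] + contrib
    mean(contrib > threshold * total) > prob
  } else {
    hpdi(vs)[1] > threshold
  }
}

#' Residual-structure misspecification experiment
#'
#' Quantifies the bias in individual slope-variance estimates — and the
#' rate at which slope variance is "detected" — when the heterogeneous
#' residual structure of a random-regression model groups years by decade
#' (calendar blocks) instead of by temperature, or assumes homogeneity.
#' For each replicate a population is simulated (by default with zero true
#' slope variance and residual standard deviations increasing with
#' temperature), and the same random-regression model (individual
#' intercepts and slopes, year effects, no pedigree) is fitted once per
#' grouping scheme.
#'
#' When residual variance genuinely rises with temperature, only the
#' temperature grouping can absorb it; decade or homogeneous groupings
#' push that environment-linked variance into the individual slopes.
#'
#' @param config an [sim_config()]; the default experiment population is
#'   set by the caller (500 females / 30 years in the shipped analyses).
#' @param schemes subset of `c("decade", "temperature", "homogeneous")`.
#' @param n_reps replicate datasets (default 100).
#' @param n_groups residual groups for the decade/temperature schemes
#'   (default `round(n_years / 10)`).
#' @param mcmc settings per fit (modest defaults; one fit per scheme per
#'   replicate).
#' @param seed integer seed.
#' @param detect_args list passed to [detect_slope_variance()].
#' @return `rn_residual_experiment`: `per_rep` tidy data.frame (scheme,
#'   rep, slope_var, slope_var_contribution, detected), `summary`
#'   (per-scheme mean/sd of estimates and detection rate), `n_failed`,
#'   and the config echo.
#' @export
run_residual_experiment <- function(config = sim_config(n_founders = 28,
                                                        n_years = 30,
                                                        sigma2_B = 0,
                                                        cov_AB = 0,
                                                        sigma2_PE_slope = 0,
                                                        cov_PE = 0),
                                    schemes = c("decade", "temperature", "homogeneous"),
                                    n_reps = 100,
                                    n_groups = max(1L, round(config$n_years / 10)),
                                    mcmc = mcmc_settings(n_iter = 2200, burn = 700,
                                                         thin = 3),
                                    seed = 1L, detect_args = list()) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (config$resid_temp_dependence &&
      is.unsorted(config$residual_sd_by_group))
    stop("residual sds must increase with temperature for this experiment")
  # per-replicate sub-seeds, kept inside the 32-bit integer range
  sub_seed <- function(rep) {
    as.integer((as.numeric(seed) * 1000 + rep) %% 2147483647)
  }
  rows <- list()
  n_failed <- 0L
  for (rep in seq_len(n_reps)) {
    d <- simulate_dataset(config, seed = seed + rep)
    env <- d$environments
    for (sch in schemes) {
      spec <- model_spec("rram", additive = FALSE, nestbox_effect = FALSE,
                         n_resid_groups = if (sch == "homogeneous") 1L else n_groups)
      # decade grouping bypasses the temperature ranking: contiguous
      # calendar blocks of years
      rec <- d$records
      if (sch == "decade") {
        env2 <- env
        # rank by year instead of temperature so the equal-count blocks
        # are calendar decades
        env2$cue_temp <- env2$year
        grp <- assign_residual_groups(env2, n_groups)
        fit <- fit_model_grouped(rec, env, spec, grp, mcmc,
                                 seed = sub_seed(rep))
      } else {
        fit <- tryCatch(
          fit_model(rec, env, spec, mcmc = mcmc, seed = sub_seed(rep)),
          error = function(e) NULL)
      }
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      vs <- stats::median(fit$samples[, "V_pe_slope"])
      contrib <- stats::median(slope_variance_contribution(
        fit$samples[, "V_pe_slope"], fit$centred_temps))
      det <- do.call(detect_slope_variance, c(list(fit), detect_args))
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = sch, rep = rep, slope_var = vs,
        slope_var_contribution = contrib, detected = det)
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$scheme), function(g)
    data.frame(scheme = g$scheme[1], n = nrow(g),
               mean_slope_var = mean(g$slope_var),
               sd_slope_var = stats::sd(g$slope_var),
               detection_rate = mean(g$detected))))
  rownames(summ) <- NULL
  structure(list(per_rep = per_rep, summary = summ, n_failed = n_failed,
                 config = config, n_reps = n_reps, seed = seed),
            class = "rn_residual_experiment")
}

# fit_model variant taking an explicit year->residual-group map
fit_model_grouped <- function(records, environments, spec, group_by_year,
                              mcmc, seed) {
  d <- build_design(records, environments, spec)
  rg <- as.integer(group_by_year[as.character(d$rec$year)]) - 1L
  fit_model_raw(records, environments, spec, d, rg, mcmc, seed)
}

# low-level refit with overridden residual-group vector
fit_model_raw <- function(records, environments, spec, d, rg, mcmc, seed,
                          px = TRUE) {
  set.seed(seed)
  prior <- default_prior(px)
  control <- c(mcmc, list(fix_resid = NULL, fix_pe_cov = NULL, px = px))
  Ainv <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(0, 0))
  out <- rram_gibbs(d$rec$laying_date, d$X, d$fem, d$tc, rg, d$yr, d$nb,
                    length(d$fem_levels), d$n_yr, d$n_nb,
                    length(unique(rg)), spec$individual_slope, Ainv,
                    integer(0), prior, control)
  cn <- c(colnames(d$X), c("V_pe_int", "cov_pe", "V_pe_slope"),
          if (d$n_yr > 0) "V_year", if (d$n_nb > 0) "V_nestbox",
          paste0("V_resid_g", seq_len(length(unique(rg)))))
  samples <- out$samples
  colnames(samples) <- cn
  summ <- do.call(rbind, lapply(cn, function(nm)
    as.data.frame(posterior_summary(samples[, nm]))))
  summ <- cbind(parameter = cn, summ)
  structure(list(samples = samples, summary = summ, spec = spec,
                 grand_mean_temp = d$grand_mean,
                 centred_temps = d$tc,
                 n_females = length(d$fem_levels), n_records = nrow(d$rec),
                 n_jitter = out$n_jitter, mcmc = mcmc, seed = seed),
            class = "rn_fit")
}

#' One generation of truth-known selection on the reaction norm
#'
#' Forward-simulation oracle for the breeder's equation: parents carry
#' known breeding values (intercept, slope) drawn from G, express
#' `z = A + B x + e` in a single environment `x`, are selected as parents
#' with probability proportional to Gaussian fitness
#' `exp(-(z - theta)^2 / (2 omega^2))`, and offspring breeding values are
#' midparent plus Mendelian noise. The realized change in mean breeding
#' values is returned alongside the sample of parental phenotypes, so the
#' prediction `G (1, x)' beta_z` can be checked against it.
#'
#' @param G 2x2 additive covariance matrix.
#' @param x_j centred environmental value.
#' @param theta,omega optimum and width of the fitness surface (on the
#'   phenotype scale).
#' @param n_parents,n_offspring sample sizes.
#' @param sigma_e residual phenotypic sd.
#' @return list `delta_bv` (realized 2-vector change), `z` (parent
#'   phenotypes), `parent_bv` (n x 2), `W` (expected fitnesses).
#' @export
simulate_selection_generation <- function(G, x_j, theta, omega,
                                          n_parents = 500,
                                          n_offspring = 500, sigma_e = 3) {
  bv <- matrix(stats::rnorm(2 * n_parents), ncol = 2) %*% chol_psd(as.matrix(G))
  z <- bv[, 1] + bv[, 2] * x_j + stats::rnorm(n_parents, 0, sigma_e)
  W <- exp(-(z - theta)^2 / (2 * omega^2))
  dam <- sample.int(n_parents, n_offspring, replace = TRUE, prob = W)
  sire <- sample.int(n_parents, n_offspring, replace = TRUE, prob = W)
  off <- (bv[dam, ] + bv[sire, ]) / 2 +
    matrix(stats::rnorm(2 * n_offspring), ncol = 2) %*% chol_psd(as.matrix(G) / 2)
  list(delta_bv = colMeans(off) - colMeans(bv), z = z, parent_bv = bv, W = W)
}
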