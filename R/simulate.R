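#' Simulate an overlapping-generations pedigree with annual breeder sets
#'
#' Maintains a breeding population of `n_founders` females (and as many
#' males) for `n_years`. Each year, adults survive with probability
#' `adult_survival`; each vacancy is filled by a locally born yearling
#' (a "recruit", with both parents drawn from a pair that bred the previous
#' year) with probability `recruitment_rate`, and otherwise by an immigrant,
#' who enters the pedigree as a new founder. Females are re-paired with a
#' random male every year; recruits may therefore be full or half sibs.
#'
#' Cohort is the birth year: founders and immigrants are assigned the year
#' before their first breeding season, so every parent's cohort is strictly
#' earlier than its offspring's.
#'
#' @param config an [sim_config()] object.
#' @return a list of class `rn_pedigree_sim`:
#'   \describe{
#'     \item{pedigree}{data.frame `id`, `dam`, `sire` (NA for founders and
#'       immigrants), `cohort`, `sex`.}
#'     \item{breeders}{data.frame `year`, `female_id`, `male_id`, `nestbox`,
#'       `status` (founder/survivor/recruit/immigrant), `age_class`.}
#'   }
#'   The per-year fraction of breeding females that are locally born
#'   first-year birds is recoverable with [p_recr_by_year()].
#' @export
simulate_pedigree <- function(config) {
  validate_config(config)
  K <- config$n_founders
  years <- seq(config$year_start, length.out = config$n_years)

  next_id <- 1L
  new_ids <- function(n) {
    ids <- sprintf("I%05d", seq.int(next_id, length.out = n))
    next_id <<- next_id + n
    ids
  }

  ped <- list() # rows appended as individuals enter
  add_ind <- function(id, dam, sire, cohort, sex) {
    ped[[length(ped) + 1L]] <<- data.frame(
      id = id, dam = dam, sire = sire, cohort = cohort, sex = sex,
      stringsAsFactors = FALSE)
  }

  founders_f <- new_ids(K)
  founders_m <- new_ids(K)
  add_ind(founders_f, NA_character_, NA_character_, years[1] - 1L, "F")
  add_ind(founders_m, NA_character_, NA_character_, years[1] - 1L, "M")
  cohort_of <- stats::setNames(rep(years[1] - 1L, 2 * K), c(founders_f, founders_m))

  cur_f <- founders_f
  cur_m <- founders_m
  status_f <- rep("founder", K)
  prev_pairs <- NULL
  breeders <- vector("list", length(years))

  for (t in seq_along(years)) {
    yr <- years[t]
    if (t > 1L) {
      surv_f <- cur_f[stats::runif(length(cur_f)) < config$adult_survival]
      surv_m <- cur_m[stats::runif(length(cur_m)) < config$adult_survival]
      fill <- function(survivors, sex) {
        n_new <- K - length(survivors)
        if (n_new == 0L)
          return(list(ids = survivors, status = rep("survivor", length(survivors))))
        has_pairs <- !is.null(prev_pairs) && nrow(prev_pairs) > 0L
        local <- has_pairs & (stats::runif(n_new) < config$recruitment_rate)
        ids <- new_ids(n_new)
        dam <- rep(NA_character_, n_new)
        sire <- rep(NA_character_, n_new)
        if (any(local)) {
          pick <- sample.int(nrow(prev_pairs), sum(local), replace = TRUE)
          dam[local] <- prev_pairs$female[pick]
          sire[local] <- prev_pairs$male[pick]
        }
        add_ind(ids, dam, sire, yr - 1L, sex)
        cohort_of[ids] <<- yr - 1L
        list(ids = c(survivors, ids),
             status = c(rep("survivor", length(survivors)),
                        ifelse(local, "recruit", "immigrant")))
      }
      ff <- fill(surv_f, "F")
      mm <- fill(surv_m, "M")
      cur_f <- ff$ids; status_f <- ff$status
      cur_m <- mm$ids
    }
    if (length(cur_f) == 0L)
      stop("population went extinct in year ", yr)
    mates <- sample(cur_m, length(cur_f), replace = FALSE)
    boxes <- sample.int(config$n_nestbox, length(cur_f),
                        replace = config$n_nestbox < length(cur_f))
    age <- ifelse(yr - cohort_of[cur_f] == 1L, "first-year", "older")
    breeders[[t]] <- data.frame(
      year = yr, female_id = cur_f, male_id = mates,
      nestbox = sprintf("NB%03d", boxes),
      status = status_f, age_class = age, stringsAsFactors = FALSE)
    prev_pairs <- data.frame(female = cur_f, male = mates,
                             stringsAsFactors = FALSE)
  }

  structure(list(pedigree = do.call(rbind, ped),
                 breeders = do.call(rbind, breeders)),
            class = "rn_pedigree_sim")
}

#' Per-year recruit fraction of the breeding population
#'
#' `p_recr(j)` is the fraction of breeding females in year `j` that are
#' locally born first-year birds; it is the generation-time correction used
#' by the reaction-norm breeder's equation.
#'
#' @param breeders the `breeders` table from [simulate_pedigree()].
#' @return data.frame with columns `year` and `p_recr`.
#' @export
p_recr_by_year <- function(breeders) {
  agg <- stats::aggregate(status ~ year, data = breeders,
                          FUN = function(s) mean(s == "recruit"))
  names(agg)[2] <- "p_recr"
  agg
}

#' Simulate annual cue-window temperatures and caterpillar peak dates
#'
#' Cue temperature is Normal(mean + trend * (year - start), sd); the
#' caterpillar biomass peak date is linear in the cue temperature plus
#' Gaussian noise; the optimal laying date is the peak date minus the
#' rearing lag (`optimum_offset`, default 33 days).
#'
#' @param config an [sim_config()] object.
#' @return data.frame `year`, `cue_temp`, `peak_date`,
#'   `optimal_laying_date`, `excluded` (all FALSE; flag years manually to
#'   drop them from optimum regressions).
#' @export
simulate_environments <- function(config) {
  validate_config(config)
  years <- seq(config$year_start, length.out = config$n_years)
  cue <- config$mean_cue_temp + config$temp_trend * (years - config$year_start) +
    stats::rnorm(length(years), 0, config$sd_cue_temp)
  peak <- config$peak_intercept + config$peak_slope * cue +
    stats::rnorm(length(years), 0, config$peak_resid_sd)
  data.frame(year = years, cue_temp = cue, peak_date = peak,
             optimal_laying_date = optimal_laying_date(peak, config$optimum_offset),
             excluded = FALSE)
}

# rank years into n contiguous equal-count temperature groups (coldest first)
year_temp_groups <- function(environments, n_groups) {
  if (n_groups == 1L)
    return(stats::setNames(rep(1L, nrow(environments)), environments$year))
  ord <- order(environments$cue_temp, environments$year)
  grp <- integer(nrow(environments))
  grp[ord] <- rep(seq_len(n_groups),
                  times = tabulate(cut(seq_along(ord), n_groups, labels = FALSE),
                                   nbins = n_groups))
  stats::setNames(grp, environments$year)
}

#' Simulate breeding records with known reaction-norm truth
#'
#' Assembles one laying-date record per breeding female and year from the
#' random-regression data-generating model: fixed effects (overall mean, age
#' class, population plasticity slope on grand-mean-centred temperature),
#' additive-genetic and permanent-environment intercepts and slopes, year
#' and nest-box effects, and a residual whose standard deviation is taken
#' from the record's temperature group when `resid_temp_dependence` is on.
#' Breeding values flow through the pedigree: founders are MVN(0, G) and
#' offspring are midparent plus a Mendelian deviation MVN(0, G/2)
#' (non-inbred approximation). Expected recruits follow Gaussian stabilizing
#' selection around the year's optimal laying date,
#' `fitness_max * exp(-(z - LDtheta)^2 / (2 fitness_width^2))`, and realized
#' recruits are negative binomial with the configured dispersion.
#'
#' A configurable fraction of records has the female identity blanked
#' (biased towards extreme laying dates) and a random fraction is flagged as
#' brood-manipulated with a multiplicative effect on expected recruits.
#'
#' @param pedsim output of [simulate_pedigree()].
#' @param environments output of [simulate_environments()] covering the same
#'   years.
#' @param config the same [sim_config()] object.
#' @return list of class `rn_synthetic`:
#'   \describe{
#'     \item{records}{data.frame `female_id` (NA = unknown identity), `year`,
#'       `nestbox`, `laying_date` (April days), `age_class`, `recruits`,
#'       `manipulated`.}
#'     \item{truth}{data.frame of per-individual true values: `id`, `A`, `B`
#'       (additive intercept/slope), `a_pe`, `b_pe` (permanent environment;
#'       NA for males).}
#'     \item{year_effects, nestbox_effects}{the simulated random effects.}
#'     \item{grand_mean_temp}{the temperature used for centring.}
#'   }
#' @export
simulate_breeding_data <- function(pedsim, environments, config) {
  validate_config(config)
  ped <- pedsim$pedigree
  br <- pedsim$breeders
  if (!all(br$year %in% environments$year))
    stop("environments do not cover all breeding years")

  G <- matrix(c(config$sigma2_A, config$cov_AB,
                config$cov_AB, config$sigma2_B), 2)
  PE <- matrix(c(config$sigma2_PE_int, config$cov_PE,
                 config$cov_PE, config$sigma2_PE_slope), 2)

  # breeding values through the pedigree, in cohort (hence topological) order
  n <- nrow(ped)
  ord <- order(ped$cohort)
  idx <- stats::setNames(seq_len(n), ped$id)
  bv <- matrix(0, n, 2)
  cG <- chol_psd(G)
  cM <- chol_psd(G / 2)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  for (r in ord) {
    d <- ped$dam[r]; s <- ped$sire[r]
    if (is.na(d)) {
      bv[r, ] <- z[r, ] %*% cG
    } else {
      bv[r, ] <- (bv[idx[[d]], ] + bv[idx[[s]], ]) / 2 + z[r, ] %*% cM
    }
  }

  females <- ped$id[ped$sex == "F"]
  pe <- matrix(stats::rnorm(2 * length(females)), ncol = 2) %*% chol_psd(PE)
  rownames(pe) <- females

  env <- environments[match(sort(unique(br$year)), environments$year), ]
  grand_mean <- mean(env$cue_temp)
  yeff <- stats::setNames(stats::rnorm(nrow(env), 0, sqrt(config$sigma2_year)),
                          env$year)
  nbeff <- stats::setNames(stats::rnorm(config$n_nestbox, 0,
                                        sqrt(config$sigma2_nestbox)),
                           sprintf("NB%03d", seq_len(config$n_nestbox)))

  ngrp <- length(config$residual_sd_by_group)
  if (config$resid_temp_dependence && ngrp > 1L) {
    grp <- year_temp_groups(env, ngrp)
    sd_year <- stats::setNames(config$residual_sd_by_group[grp], names(grp))
  } else {
    sd_year <- stats::setNames(rep(config$residual_sd_by_group[1], nrow(env)),
                               env$year)
  }

  tc <- env$cue_temp[match(br$year, env$year)] - grand_mean
  ldtheta <- optimal_laying_date(env$peak_date, config$optimum_offset)[
    match(br$year, env$year)]
  age_eff <- ifelse(br$age_class == "first-year", config$age_young_effect, 0)
  A <- bv[idx[br$female_id], 1]
  B <- bv[idx[br$female_id], 2]
  a_pe <- pe[br$female_id, 1]
  b_pe <- pe[br$female_id, 2]
  zld <- config$mean_laying_date + age_eff + A + a_pe +
    (config$pop_slope + B + b_pe) * tc +
    yeff[as.character(br$year)] + nbeff[br$nestbox] +
    stats::rnorm(nrow(br), 0, sd_year[as.character(br$year)])

  manipulated <- stats::runif(nrow(br)) < config$manipulated_frac
  mu <- config$fitness_max *
    exp(-(zld - ldtheta)^2 / (2 * config$fitness_width^2)) *
    ifelse(manipulated, config$manipulated_fitness_factor, 1)
  recruits <- stats::rnbinom(nrow(br), size = config$overdispersion, mu = mu)

  records <- data.frame(
    female_id = br$female_id, year = br$year, nestbox = br$nestbox,
    laying_date = zld, age_class = br$age_class,
    recruits = recruits, manipulated = manipulated,
    stringsAsFactors = FALSE)

  # unknown-identity records, biased towards extreme laying dates
  n_unk <- round(config$unknown_id_frac * nrow(records))
  if (n_unk > 0L) {
    w <- abs(zld - stats::median(zld)) + 0.1
    unk <- sample.int(nrow(records), n_unk, prob = w)
    records$female_id[unk] <- NA_character_
    records$age_class[unk] <- "unknown"
  }

  truth <- data.frame(id = ped$id, sex = ped$sex,
                      A = bv[, 1], B = bv[, 2],
                      a_pe = pe[match(ped$id, females), 1],
                      b_pe = pe[match(ped$id, females), 2],
                      stringsAsFactors = FALSE)

  structure(list(records = records, truth = truth,
                 year_effects = yeff, nestbox_effects = nbeff,
                 grand_mean_temp = grand_mean),
            class = "rn_synthetic")
}

# Cholesky factor that tolerates semi-definite 2x2 inputs (zero variances)
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}

#' One-call synthetic dataset
#'
#' Runs [simulate_pedigree()], [simulate_environments()] and
#' [simulate_breeding_data()] under the config's seed (or an explicit one)
#' and returns everything downstream stages need.
#'
#' @param config an [sim_config()] object.
#' @param seed overrides `config$seed` when given.
#' @return list with `pedigree`, `breeders`, `environments`, `records`,
#'   `truth`, `year_effects`, `nestbox_effects`, `grand_mean_temp`, `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n_founders = 20, n_years = 8))
#' head(d$records)
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  set.seed(seed)
  pedsim <- simulate_pedigree(config)
  env <- simulate_environments(config)
  sim <- simulate_breeding_data(pedsim, env, config)
  c(list(pedigree = pedsim$pedigree, breeders = pedsim$breeders,
         environments = env, config = config, seed = seed),
    unclass(sim))
}

#' Synthetic daily temperature series consistent with annual cue means
#'
#' Generates a smooth seasonal daily mean-temperature curve with AR(1) noise
#' for each year, then shifts each year's series additively so that its mean
#' over the cue window (day-of-year `window[1]`..`window[2]`, default
#' March 11 to April 20) equals the year's `cue_temp`. Useful for exercising
#' the sliding-window cue search on data whose best window is known.
#'
#' @param environments output of [simulate_environments()].
#' @param doy_range day-of-year span of the series (non-leap convention).
#' @param window cue window whose mean is pinned to `cue_temp`.
#' @param ar,sd_day AR(1) coefficient and innovation sd of daily noise.
#' @return data.frame `year`, `doy`, `date` (ISO), `temperature`.
#' @export
simulate_daily_temperatures <- function(environments, doy_range = c(32, 151),
                                        window = c(70, 110), ar = 0.7,
                                        sd_day = 2.5) {
  doys <- seq(doy_range[1], doy_range[2])
  out <- lapply(seq_len(nrow(environments)), function(i) {
    season <- 2 + 10 * (doys - doy_range[1]) / diff(doy_range) # spring ramp
    e <- stats::filter(stats::rnorm(length(doys), 0, sd_day), ar,
                       method = "recursive")
    temp <- season + as.numeric(e)
    inwin <- doys >= window[1] & doys <= window[2]
    temp <- temp + (environments$cue_temp[i] - mean(temp[inwin]))
    data.frame(year = environments$year[i], doy = doys,
               date = as.Date(doys - 1,
                              origin = paste0(environments$year[i], "-01-01")),
               temperature = temp)
  })
  do.call(rbind, out)
}
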