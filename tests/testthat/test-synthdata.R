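test_that("config validation enforces variance and probability constraints", {
  expect_s3_class(sim_config(), "rn_config")
  expect_error(sim_config(sigma2_A = -1))
  expect_error(sim_config(cov_AB = 10), "positive semi-definite")
  expect_error(sim_config(cov_PE = -10), "positive semi-definite")
  expect_error(sim_config(n_years = 1))
  expect_error(sim_config(residual_sd_by_group = numeric(0)))
  expect_error(sim_config(nonsense_field = 1), "unknown config field")
})

test_that("pedigree simulation respects cohort ordering and demography", {
  d <- small_dataset()
  ped <- validate_pedigree(d$pedigree)
  idx <- setNames(ped$cohort, ped$id)
  nonf <- !is.na(ped$dam)
  expect_true(all(idx[ped$dam[nonf]] < ped$cohort[nonf]))
  expect_true(all(idx[ped$sire[nonf]] < ped$cohort[nonf]))
  # one record per female per year
  br <- d$breeders
  expect_false(any(duplicated(br[, c("female_id", "year")])))
})

test_that("with full survival and no recruitment all breeders are founders", {
  set.seed(5)
  ps <- simulate_pedigree(sim_config(n_founders = 15, n_years = 6,
                                     adult_survival = 1, recruitment_rate = 0))
  first <- ps$breeders$female_id[ps$breeders$year == min(ps$breeders$year)]
  for (y in unique(ps$breeders$year)) {
    expect_setequal(ps$breeders$female_id[ps$breeders$year == y], first)
  }
  pr <- p_recr_by_year(ps$breeders)
  expect_equal(pr$p_recr, rep(0, nrow(pr)))
})

test_that("realized recruit fraction matches demographic bookkeeping", {
  # independent oracle: a vacancy arises with prob (1 - survival) and is
  # filled locally with prob recruitment_rate, so E[p_recr] =
  # (1 - adult_survival) * recruitment_rate once past the founder year
  cfg <- sim_config(n_founders = 40, n_years = 10,
                    adult_survival = 0.5, recruitment_rate = 0.7)
  set.seed(77)
  means <- replicate(60, {
    pr <- p_recr_by_year(simulate_pedigree(cfg)$breeders)
    mean(pr$p_recr[-1])
  })
  expected <- (1 - cfg$adult_survival) * cfg$recruitment_rate
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 4 * mc_se + 0.005)
})

test_that("noise-free environments lie exactly on the linear predictor", {
  cfg <- sim_config(n_founders = 5, n_years = 8, sd_cue_temp = 0,
                    peak_resid_sd = 0, temp_trend = 0)
  set.seed(1)
  env <- simulate_environments(cfg)
  expect_equal(env$cue_temp, rep(cfg$mean_cue_temp, 8))
  expect_equal(env$peak_date,
               rep(cfg$peak_intercept + cfg$peak_slope * cfg$mean_cue_temp, 8))
  expect_equal(env$optimal_laying_date, env$peak_date - 33)

  # zero peak noise but varying temperature: regression recovers the slope
  cfg2 <- sim_config(n_founders = 5, n_years = 20, peak_resid_sd = 0)
  env2 <- simulate_environments(cfg2)
  expect_equal(unname(coef(lm(peak_date ~ cue_temp, env2))[2]),
               cfg2$peak_slope, tolerance = 1e-10)
})

test_that("the default optimum-regression slope is -3.15 days per degree", {
  expect_equal(sim_config()$peak_slope, -3.15)
  expect_equal(sim_config()$optimum_offset, 33)
})

test_that("degenerate variances give exactly the fixed-effect predictor", {
  cfg <- sim_config(n_founders = 10, n_years = 5,
                    sigma2_A = 0, sigma2_B = 0, cov_AB = 0,
                    sigma2_PE_int = 0, sigma2_PE_slope = 0, cov_PE = 0,
                    sigma2_year = 0, sigma2_nestbox = 0,
                    residual_sd_by_group = 0, resid_temp_dependence = FALSE,
                    unknown_id_frac = 0)
  d <- simulate_dataset(cfg, seed = 3)
  env <- d$environments
  tc <- env$cue_temp[match(d$records$year, env$year)] - d$grand_mean_temp
  pred <- cfg$mean_laying_date +
    ifelse(d$records$age_class == "first-year", cfg$age_young_effect, 0) +
    cfg$pop_slope * tc
  expect_equal(d$records$laying_date, pred, tolerance = 1e-12)
})

test_that("founder breeding-value variance matches the configured G", {
  cfg <- sim_config(n_founders = 1000, n_years = 2, recruitment_rate = 0)
  d <- simulate_dataset(cfg, seed = 9)
  founders <- is.na(d$pedigree$dam)
  vA <- var(d$truth$A[founders])
  expect_lt(abs(vA - cfg$sigma2_A) / cfg$sigma2_A, 0.10)
  # parent-offspring regression of intercept breeding values: slope ~ 0.5
  cfg2 <- sim_config(n_founders = 150, n_years = 12, recruitment_rate = 1,
                     adult_survival = 0.3)
  d2 <- simulate_dataset(cfg2, seed = 10)
  ped <- d2$pedigree
  bv <- setNames(d2$truth$A, d2$truth$id)
  off <- which(!is.na(ped$dam))
  sl <- coef(lm(bv[ped$id[off]] ~ bv[ped$dam[off]]))[2]
  expect_lt(abs(sl - 0.5), 0.08)
})

test_that("residual heterogeneity shows up as higher warm-group variance", {
  cfg <- sim_config(n_founders = 120, n_years = 24,
                    sigma2_year = 0, residual_sd_by_group = c(2, 3, 5, 8))
  d <- simulate_dataset(cfg, seed = 21)
  grp <- assign_residual_groups(d$environments, 4)
  g <- grp[as.character(d$records$year)]
  v_cold <- var(d$records$laying_date[g == 1])
  v_warm <- var(d$records$laying_date[g == 4])
  expect_gt(v_warm, v_cold)
})

test_that("zero intercept-slope covariance yields uncorrelated breeding values", {
  cfg <- sim_config(n_founders = 1500, n_years = 2, cov_AB = 0)
  d <- simulate_dataset(cfg, seed = 13)
  r <- cor(d$truth$A, d$truth$B)
  expect_lt(abs(r), 0.05)
})

test_that("the same seed reproduces identical output", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg, seed = 404)
  d2 <- simulate_dataset(cfg, seed = 404)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$environments, d2$environments)
})

test_that("unknown-identity and manipulation flags hit their configured rates", {
  cfg <- sim_config(n_founders = 100, n_years = 20,
                    unknown_id_frac = 0.1, manipulated_frac = 0.3)
  d <- simulate_dataset(cfg, seed = 31)
  expect_equal(mean(is.na(d$records$female_id)), 0.1, tolerance = 0.02)
  expect_equal(mean(d$records$manipulated), 0.3, tolerance = 0.05)
  # blanking is biased towards extreme laying dates
  dev <- abs(d$records$laying_date - median(d$records$laying_date))
  expect_gt(mean(dev[is.na(d$records$female_id)]), mean(dev))
})
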