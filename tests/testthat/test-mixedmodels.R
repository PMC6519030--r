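test_that("within-individual centring splits and reconstructs temperature", {
  cw <- center_within_individual(8, "a")
  expect_equal(cw$within, 0)
  expect_equal(cw$between, 8)
  cw2 <- center_within_individual(c(8, 10), c("a", "a"))
  expect_equal(cw2$within, c(-1, 1))
  expect_equal(cw2$between, c(9, 9))
  set.seed(2)
  temp <- rnorm(200)
  ind <- sample(letters[1:20], 200, replace = TRUE)
  cw3 <- center_within_individual(temp, ind)
  expect_equal(cw3$within + cw3$between, temp)
  sums <- tapply(cw3$within, ind, sum)
  expect_true(all(abs(sums) < 1e-10))
})

test_that("residual groups are equal-count blocks along the temperature rank", {
  env44 <- data.frame(year = 1:44, cue_temp = sin(1:44) * 3 + 8)
  expect_equal(max(1L, round(nrow(env44) / 10)), 4L) # the default rule
  g <- assign_residual_groups(env44)
  expect_equal(as.integer(table(g)), rep(11L, 4))
  # groups are ordered along temperature
  expect_true(all(diff(env44$cue_temp[order(env44$cue_temp)][c(11, 12)]) >= 0))
  env4 <- data.frame(year = 2001:2004, cue_temp = c(3, 5, 7, 9))
  g2 <- assign_residual_groups(env4, 2)
  expect_equal(unname(g2), c(1L, 1L, 2L, 2L))
})

test_that("slope-variance contribution is variance times slope variance", {
  expect_equal(slope_variance_contribution(0, rnorm(10)), 0)
  t2 <- c(-1, 1) # sample variance exactly 2
  expect_equal(slope_variance_contribution(1, t2), 2)
  set.seed(3)
  s2 <- runif(1); tt <- rnorm(30)
  expect_equal(slope_variance_contribution(s2, tt), s2 * var(tt))
})

test_that("posterior summaries behave on constant, uniform and skewed chains", {
  cc <- rep(3.5, 200)
  ps <- posterior_summary(cc)
  expect_equal(c(ps$median, ps$lower, ps$upper), c(3.5, 3.5, 3.5))
  expect_true(is.na(ps$ess))
  set.seed(4)
  u <- runif(1e4)
  h <- hpdi(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.02)
  e <- rexp(1e4)
  he <- hpdi(e, 0.95)
  expect_lt(he[1], quantile(e, 0.025)) # HPDI hugs the zero boundary
  expect_equal(ess(rnorm(1000)), 1000, tolerance = 350)
})

test_that("the Gibbs sampler reproduces the conjugate closed form", {
  # one Gaussian response, known residual variance, a single random
  # intercept factor with fixed variance: the posterior of each level
  # effect is N(b/(n/s2e + 1/s2u) * (1/s2e) * sum(y), 1/(n/s2e + 1/s2u))
  set.seed(11)
  nf <- 8
  nrep <- c(2, 5, 3, 7, 1, 4, 6, 2)
  fem <- rep(seq_len(nf) - 1L, nrep)
  s2u <- 4; s2e <- 2
  u_true <- rnorm(nf, 0, sqrt(s2u))
  y <- u_true[fem + 1] + rnorm(length(fem), 0, sqrt(s2e))
  out <- rnevo:::rram_gibbs(
    y, matrix(0, length(y), 0), as.integer(fem), rep(0, length(y)),
    rep(0L, length(y)), rep(0L, length(y)), rep(0L, length(y)),
    nf, 0L, 0L, 1L, FALSE,
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0, 0)),
    integer(0),
    list(nu_pe = 1, V_pe = matrix(1), nu_g = 1, V_g = diag(2),
         a_scalar = 1, b_scalar = 1, alpha_V = 625),
    list(n_iter = 6000L, burn = 1000L, thin = 1L,
         fix_resid = s2e, fix_pe_cov = matrix(s2u), px = FALSE))
  # closed form per level
  sums <- tapply(y, fem, sum)
  prec <- nrep / s2e + 1 / s2u
  post_mean <- (sums / s2e) / prec
  # the sampler stores only variance components; effects are checked via
  # the predictive residual: rerun capturing residual variance is fixed,
  # so instead verify the marginal variance identity on the samples
  expect_equal(ncol(out$samples), 2) # fixed V_pe and fixed resid echoed
  expect_equal(unique(out$samples[, 1]), s2u)
  expect_equal(unique(out$samples[, 2]), s2e)
  # and check the closed form directly against an R-level Gibbs of the
  # same model using the package machinery on records
  rec <- data.frame(female_id = paste0("f", fem), year = 2000L,
                    nestbox = "NB1", laying_date = y,
                    age_class = "older", recruits = 0, manipulated = FALSE)
  env <- data.frame(year = 2000L, cue_temp = 8, peak_date = NA,
                    optimal_laying_date = NA, excluded = FALSE)
  # a single year and constant temperature: model is intercept + female
  spec <- model_spec("rram", individual_slope = FALSE, additive = FALSE,
                     year_effect = FALSE, nestbox_effect = FALSE,
                     n_resid_groups = 1)
  fit <- fit_model(rec, env, spec, mcmc = mcmc_settings(3000, 500, 1),
                   seed = 2, fix_resid = s2e, fix_pe_cov = matrix(s2u))
  # with a flat-prior intercept, the intercept posterior mean equals the
  # GLS estimate of the compound-symmetric model
  V <- diag(s2e, length(fem)) + s2u * outer(fem, fem, "==")
  ones <- rep(1, length(fem))
  gls_mean <- sum(solve(V, y)) / sum(solve(V, ones))
  gls_var <- 1 / sum(solve(V, ones))
  mu_chain <- fit$samples[, "(Intercept)"]
  expect_equal(mean(mu_chain), gls_mean, tolerance = 4 * sd(mu_chain) / sqrt(200))
  expect_equal(var(mu_chain), gls_var, tolerance = 0.35 * gls_var)
})

test_that("stored covariance samples are positive semi-definite", {
  d <- small_dataset()
  fit <- fit_model(d$records, d$environments, model_spec("rram"),
                   pedigree = d$pedigree,
                   mcmc = mcmc_settings(1500, 500, 2), seed = 5)
  s <- fit$samples
  expect_true(all(s[, "V_pe_int"] >= 0))
  expect_true(all(s[, "V_pe_slope"] >= 0))
  det_pe <- s[, "V_pe_int"] * s[, "V_pe_slope"] - s[, "cov_pe"]^2
  det_a <- s[, "V_a_int"] * s[, "V_a_slope"] - s[, "cov_a"]^2
  expect_true(all(det_pe >= -1e-8))
  expect_true(all(det_a >= -1e-8))
  expect_true(all(s[, grep("V_resid", colnames(s))] > 0))
})

test_that("true zero variance components give near-zero, zero-bound medians", {
  cfg <- sim_config(n_founders = 60, n_years = 15,
                    sigma2_A = 0, sigma2_B = 0, cov_AB = 0,
                    sigma2_PE_int = 0, sigma2_PE_slope = 0, cov_PE = 0,
                    sigma2_nestbox = 0,
                    residual_sd_by_group = 4, resid_temp_dependence = FALSE,
                    unknown_id_frac = 0)
  d <- simulate_dataset(cfg, seed = 19)
  fit <- fit_model(d$records, d$environments,
                   model_spec("rram", additive = FALSE, nestbox_effect = FALSE,
                              n_resid_groups = 1),
                   mcmc = mcmc_settings(3000, 1000, 2), seed = 6)
  s <- fit$summary
  vi <- s[s$parameter == "V_pe_int", ]
  vs <- s[s$parameter == "V_pe_slope", ]
  expect_lt(vi$median, 1.5) # small against a residual variance of 16
  expect_lt(vs$median, 0.25)
  expect_lt(vi$lower, 0.1) # HPDIs abut zero
  expect_lt(vs$lower, 0.02)
})

test_that("the bivariate model recovers a planted elevation-fitness covariance", {
  cfg <- sim_config(n_founders = 60, n_years = 16, peak_intercept = 68,
                    fitness_width = 8, unknown_id_frac = 0,
                    manipulated_frac = 0)
  d <- simulate_dataset(cfg, seed = 3)
  fit <- fit_selection_rrm(d$records, d$environments,
                           mcmc = mcmc_settings(6000, 1500, 5), seed = 2)
  s <- fit$summary
  cov_il <- s[s$parameter == "cov_int_lrs", ]
  expect_lt(cov_il$median, 0) # later elevation, fewer recruits
  expect_lt(cov_il$upper, 0) # decisively negative
  expect_gt(s[s$parameter == "V_ld_int", "median"], 1)
  # only females with >= 2 attempts enter
  expect_true(fit$n_records >= 2 * fit$n_females)
})

test_that("doubling iterations leaves well-identified posteriors unchanged", {
  d <- small_dataset()
  spec <- model_spec("rram", additive = FALSE, nestbox_effect = FALSE)
  f1 <- fit_model(d$records, d$environments, spec,
                  mcmc = mcmc_settings(2500, 500, 2), seed = 7)
  f2 <- fit_model(d$records, d$environments, spec,
                  mcmc = mcmc_settings(5000, 1000, 4), seed = 8)
  for (p in c("temp_c", "V_resid_g1")) {
    m1 <- f1$summary[f1$summary$parameter == p, "median"]
    m2 <- f2$summary[f2$summary$parameter == p, "median"]
    expect_equal(m1, m2, tolerance = 0.15 * abs(m1) + 0.05)
  }
})
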