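test_that("optimal laying date is the peak date minus the rearing lag", {
  expect_equal(optimal_laying_date(120), 87)
  expect_equal(optimal_laying_date(33), 0)
  expect_equal(optimal_laying_date(c(100, 140)), c(67, 107))
  expect_equal(optimal_laying_date(100, offset = 30), 70)
  expect_error(optimal_laying_date(NA))
})

test_that("hindcasting fills missing peaks by the calibration regression", {
  env <- data.frame(year = 1:10, cue_temp = seq(5, 9.5, 0.5),
                    peak_date = 90 - 3 * seq(5, 9.5, 0.5),
                    optimal_laying_date = NA, excluded = FALSE)
  env$peak_date[1:4] <- NA
  filled <- hindcast_peaks(env)
  expect_equal(filled$peak_date, 90 - 3 * env$cue_temp, tolerance = 1e-10)
  expect_equal(filled$optimal_laying_date, filled$peak_date - 33)

  # extrapolation warning
  env2 <- env
  env2$cue_temp[1] <- 2 # far below the calibration range
  expect_warning(hindcast_peaks(env2), "outside the calibration range")

  # too few calibration points
  env3 <- env
  env3$peak_date[1:8] <- NA
  expect_error(hindcast_peaks(env3), "at least 3")

  # noisy data: filled values equal an independent normal-equations fill
  set.seed(6)
  env4 <- data.frame(year = 1:12, cue_temp = rnorm(12, 8),
                     peak_date = NA_real_, optimal_laying_date = NA,
                     excluded = FALSE)
  env4$peak_date <- 80 - 3 * env4$cue_temp + rnorm(12, 0, 2)
  env4$peak_date[1:3] <- NA
  filled4 <- hindcast_peaks(env4)
  cal <- env4[4:12, ]
  Xc <- cbind(1, cal$cue_temp)
  beta <- solve(t(Xc) %*% Xc, t(Xc) %*% cal$peak_date)
  expect_equal(filled4$peak_date[1:3],
               as.numeric(cbind(1, env4$cue_temp[1:3]) %*% beta),
               tolerance = 1e-8)
  expect_equal(filled4$peak_date[4:12], env4$peak_date[4:12]) # untouched
})

test_that("noise-free period shifts are recovered exactly", {
  env <- data.frame(year = 1:30,
                    cue_temp = rep(seq(6, 9, length.out = 15), 2),
                    excluded = FALSE)
  env$optimal_laying_date <- 100 - 3 * env$cue_temp - ifelse(env$year > 15, 5, 0)
  per <- period_definition(list(c(1, 15), c(16, 30)))
  suppressWarnings(of <- fit_optimum_by_period(env, per, n_boot = 200, seed = 1))
  est <- of$estimates
  g <- function(s) est$estimate[est$statistic == s]
  expect_equal(g("elev_diff_16-30_vs_1-15"), -5, tolerance = 1e-10)
  expect_equal(g("slope_diff_16-30_vs_1-15"), 0, tolerance = 1e-10)
  expect_equal(g("slope_1-15"), -3, tolerance = 1e-10)
  # noise-free: CI widths collapse
  d <- est[est$statistic == "elev_diff_16-30_vs_1-15", ]
  expect_lt(d$upper - d$lower, 1e-8)
})

test_that("a single linear period returns its slope and mean-temperature elevation", {
  env <- data.frame(year = 1:12, cue_temp = seq(5, 10.5, 0.5), excluded = FALSE)
  env$optimal_laying_date <- 100 - 3 * env$cue_temp
  per <- period_definition(list(c(1, 12)))
  suppressWarnings(of <- fit_optimum_by_period(env, per, n_boot = 200, seed = 2))
  est <- of$estimates
  expect_equal(est$estimate[est$statistic == "slope_1-12"], -3, tolerance = 1e-10)
  # elevation at the grand-mean temperature
  expect_equal(est$estimate[est$statistic == "elevation_1-12"],
               100 - 3 * mean(env$cue_temp), tolerance = 1e-10)
})

test_that("excluded years are dropped and degenerate designs refused", {
  env <- data.frame(year = 1:15, cue_temp = rnorm(15, 8),
                    excluded = FALSE)
  env$optimal_laying_date <- 90 - 3 * env$cue_temp
  env$excluded[7] <- TRUE
  per <- period_definition(list(c(1, 15)))
  of <- fit_optimum_by_period(env, per, n_boot = 150, seed = 3)
  expect_equal(of$n_years, 14)
  expect_equal(of$excluded_years, 7)
  env$cue_temp <- 8
  expect_error(fit_optimum_by_period(env, per, n_boot = 150, seed = 3),
               "degenerate|constant")
})

test_that("interannual optimum variance matches closed forms", {
  env <- data.frame(year = 1:8, cue_temp = rnorm(8, 8), excluded = FALSE)
  env$optimal_laying_date <- 55
  per <- period_definition(list(c(1, 8)))
  suppressWarnings(v <- optimum_variance_by_period(env, per, n_boot = 150, seed = 4))
  expect_equal(v$variance, 0)
  # two values a, b in a period: variance (a-b)^2 / 2
  env$optimal_laying_date <- rep(c(50, 58), 4)
  env2 <- env[1:2, ]
  env2$optimal_laying_date <- c(50, 58)
  # direct check of the estimator on a tiny period is the sample variance
  expect_equal(var(c(50, 58)), (50 - 58)^2 / 2)
  set.seed(5)
  # known variance 64: mean estimate over replicates within 5%
  ests <- replicate(400, var(rnorm(15, 0, 8)))
  expect_lt(abs(mean(ests) - 64) / 64, 0.05)
})

test_that("BCa intervals reduce to percentile under symmetry and respect edge cases", {
  set.seed(8)
  boot <- rnorm(4000, 10, 2) # symmetric around the estimate
  jack <- rnorm(40, 10, 0.3)
  ci <- bca_interval(10, boot, jack, 0.95)
  pct <- quantile(boot, c(0.025, 0.975), type = 6)
  width <- diff(unname(pct))
  expect_lt(abs(ci[1] - pct[1]) / width, 0.01)
  expect_lt(abs(ci[2] - pct[2]) / width, 0.01)

  expect_warning(ci0 <- bca_interval(3, rep(3, 500), rep(3, 10)), "degenerate")
  expect_equal(ci0, c(3, 3))
  expect_error(bca_interval(1, rnorm(50), rnorm(10)), "at least 100")

  # endpoints are monotone in the level
  set.seed(9)
  boot2 <- rexp(2000)
  jack2 <- rexp(30)
  lv <- c(0.5, 0.8, 0.9, 0.95)
  cis <- sapply(lv, function(l) bca_interval(1, boot2, jack2, l))
  expect_true(all(diff(cis[1, ]) <= 1e-12))
  expect_true(all(diff(cis[2, ]) >= -1e-12))
})

test_that("BCa endpoints track the analytic t-interval for a normal mean", {
  set.seed(10)
  diffs <- replicate(80, {
    x <- rnorm(50, 5, 2)
    m <- mean(x)
    boot <- replicate(400, mean(sample(x, replace = TRUE)))
    jack <- vapply(seq_along(x), function(i) mean(x[-i]), 0)
    ci <- bca_interval(m, boot, jack, 0.95)
    tt <- m + qt(c(0.025, 0.975), 49) * sd(x) / sqrt(50)
    (ci - tt) / diff(tt)
  })
  expect_lt(abs(mean(diffs[1, ])), 0.10)
  expect_lt(abs(mean(diffs[2, ])), 0.10)
})
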