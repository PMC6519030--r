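test_that("an analytic linear surface gives the closed-form gradient", {
  set.seed(1)
  z <- runif(200, 10, 40)
  a <- 5; b <- 0.05
  surf <- list(W = function(z) a + b * z,
               dW = function(z) rep(b, length(z)), gam = NULL)
  g <- directional_gradient(surf, laying_dates = z, n_boot = 0)
  expect_equal(g$beta_z, b / mean(a + b * z), tolerance = 1e-12)
  # positive scaling of fitness leaves the relative gradient unchanged
  surf3 <- list(W = function(z) 3 * (a + b * z),
                dW = function(z) rep(3 * b, length(z)), gam = NULL)
  expect_equal(directional_gradient(surf3, laying_dates = z, n_boot = 0)$beta_z,
               g$beta_z, tolerance = 1e-12)
})

test_that("a Gaussian surface matches its symbolic average derivative", {
  set.seed(2)
  z <- rnorm(300, 25, 4)
  theta <- 22; omega <- 9
  W <- function(z) exp(-(z - theta)^2 / (2 * omega^2))
  dW <- function(z) -(z - theta) / omega^2 * W(z)
  g <- directional_gradient(list(W = W, dW = dW, gam = NULL),
                            laying_dates = z, n_boot = 0)
  expect_equal(g$beta_z, mean(dW(z)) / mean(W(z)), tolerance = 1e-12)
  expect_lt(g$beta_z, 0) # mean later than optimum: selection for earlier
})

test_that("fitted surfaces recover planted signals", {
  set.seed(3)
  z <- runif(400, 10, 40)
  # log-linear signal: log W = 1 - 0.1 z (centred)
  w <- rpois(400, exp(1 - 0.1 * (z - 25)))
  surf <- fit_fitness_surface(z, w)
  # log-slope across the observed range ~ -0.1
  grid <- seq(quantile(z, 0.1), quantile(z, 0.9), length.out = 50)
  logslope <- coef(lm(log(surf$W(grid)) ~ grid))[2]
  expect_equal(unname(logslope), -0.1, tolerance = 0.1)

  # constant recruits: flat surface, zero derivative
  wk <- rep(2L, 100)
  surf2 <- fit_fitness_surface(z[1:100], wk)
  expect_equal(surf2$W(c(15, 25, 35)), rep(2, 3), tolerance = 1e-6)
  expect_equal(surf2$dW(c(15, 25, 35)), rep(0, 3), tolerance = 1e-6)
  g2 <- directional_gradient(surf2, n_boot = 20, seed = 9)
  expect_equal(g2$beta_z, 0, tolerance = 1e-6)
})

test_that("annual gradients flag bad years and are deterministic given seeds", {
  d <- small_dataset()
  rec <- d$records
  gr <- annual_gradients(rec, min_broods = 15, n_boot = 25, seed = 3)
  expect_s3_class(gr, "rn_gradients")
  expect_setequal(gr$year, unique(rec$year))
  expect_true(all(gr$flag %in% c("ok", "too_few_broods", "constant_fitness",
                                 "fit_failed")))
  ok <- gr$flag == "ok"
  expect_true(all(is.finite(gr$beta_z[ok])))
  expect_true(all(gr$se[ok] >= 0))
  # identical rerun
  gr2 <- annual_gradients(rec, min_broods = 15, n_boot = 25, seed = 3)
  expect_identical(gr, gr2)
  # a tiny year is flagged, not dropped
  gr3 <- annual_gradients(rec[rec$year <= min(rec$year) + 1, ],
                          min_broods = 1e4, n_boot = 0)
  expect_true(all(gr3$flag == "too_few_broods"))
  expect_true(all(is.na(gr3$beta_z)))
})

test_that("persistent mismatch makes every annual gradient negative", {
  # population laying far later than the optimum in every year
  cfg <- sim_config(n_founders = 80, n_years = 8, peak_intercept = 66,
                    fitness_width = 8, peak_resid_sd = 0.5,
                    manipulated_frac = 0, sigma2_year = 1)
  d <- simulate_dataset(cfg, seed = 23)
  gr <- annual_gradients(d$records, n_boot = 0)
  ok <- gr$flag %in% c("ok", "constant_fitness")
  expect_gt(sum(ok), 5)
  expect_true(all(gr$beta_z[gr$flag == "ok"] < 0))
})
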