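test_that("gradients map onto reaction-norm components as Phi' beta", {
  expect_equal(unname(map_gradients_to_rn(-0.3, 2)), c(-0.3, -0.6))
  expect_equal(unname(map_gradients_to_rn(c(0.2, 0.2), c(-1, 1))), c(0.4, 0))
  set.seed(1)
  b <- rnorm(10); x <- rnorm(10)
  Phi <- cbind(1, x)
  expect_equal(unname(map_gradients_to_rn(b, x)),
               as.numeric(t(Phi) %*% b), tolerance = 1e-12)
})

test_that("the annual response follows the reaction-norm breeder's equation", {
  expect_equal(unname(annual_response(diag(2), 0, -1, 1, sex_limited = TRUE)),
               c(-0.5, 0))
  G <- matrix(c(4.38, 0.07, 0.07, 0.02), 2)
  dg <- annual_response(G, 2, -0.05, 0.4, sex_limited = TRUE)
  expect_equal(unname(dg), c(-0.0452, -0.0011), tolerance = 1e-10)
  # uncorrected mode reduces to G beta_g for the single environment
  x <- 1.3; b <- -0.08
  expect_equal(unname(annual_response(G, x, b)),
               as.numeric(G %*% c(1, x)) * b, tolerance = 1e-12)
  # linearity in beta and p_recr
  expect_equal(annual_response(G, x, 2 * b, 0.5),
               2 * 0.5 * annual_response(G, x, b, 1), tolerance = 1e-12)
  # diagonal G and x = 0: selection cannot move the slope
  expect_equal(unname(annual_response(diag(c(4, 0.02)), 0, -0.1))[2], 0)
  expect_error(annual_response(matrix(c(1, 5, 5, 1), 2), 0, 1), "PSD")
})

test_that("first-order SE propagation collapses correctly and scales", {
  G <- matrix(c(4.38, 0.07, 0.07, 0.02), 2)
  seG0 <- matrix(0, 2, 2)
  x <- 2; b <- -0.05; seb <- 0.02
  se <- propagate_se(G, x, b, seb, seG0)
  expect_equal(unname(se), abs(as.numeric(G %*% c(1, x))) * seb,
               tolerance = 1e-12)
  expect_equal(unname(propagate_se(G, x, 0, 0, matrix(1, 2, 2))), c(0, 0))
  seG <- matrix(c(1.2, 0.16, 0.16, 0.04), 2)
  se_full <- propagate_se(G, x, b, seb, seG)
  expect_equal(unname(se_full),
               sqrt(as.numeric(G %*% c(1, x))^2 * seb^2 +
                      b^2 * c(seG[1, 1]^2 + x^2 * seG[1, 2]^2,
                              seG[2, 1]^2 + x^2 * seG[2, 2]^2)),
               tolerance = 1e-12)
  # the halving and recruit fraction scale the SE like the point estimate
  expect_equal(propagate_se(G, x, b, seb, seG, 0.4, TRUE),
               se_full * 0.2, tolerance = 1e-12)
})

test_that("SE propagation agrees with Monte-Carlo within first-order accuracy", {
  set.seed(12)
  G <- matrix(c(4.38, 0.07, 0.07, 0.02), 2)
  seG <- matrix(c(1.2, 0.16, 0.16, 0.04), 2)
  x <- 1.5; b <- -0.06; seb <- 0.015
  se <- propagate_se(G, x, b, seb, seG)
  ndraw <- 1e5
  bs <- rnorm(ndraw, b, seb)
  g1 <- rnorm(ndraw, G[1, 1], seG[1, 1]) + x * rnorm(ndraw, G[1, 2], seG[1, 2])
  g2 <- rnorm(ndraw, G[2, 1], seG[2, 1]) + x * rnorm(ndraw, G[2, 2], seG[2, 2])
  mc <- c(sd(g1 * bs), sd(g2 * bs))
  expect_lt(abs(se[1] - mc[1]) / mc[1], 0.10)
  expect_lt(abs(se[2] - mc[2]) / mc[2], 0.10)
})

test_that("cumulative responses sum and pool SEs in quadrature", {
  one <- cumulative_response(-0.2, 0.01, 3, 0.1)
  expect_equal(unname(one$cum), c(-0.2, 0.01))
  expect_equal(unname(one$lower[1]), -0.2 - 1.96 * 3)
  two <- cumulative_response(c(1, 1), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(unname(two$se[1]), 5) # 3-4-5
  expect_equal(unname(two$upper[1] - two$cum[1]), 9.8)
  set.seed(13)
  di <- rnorm(20); ds <- rnorm(20); si <- runif(20); ss <- runif(20)
  cr <- cumulative_response(di, ds, si, ss)
  expect_equal(unname(cr$cum), c(sum(di), sum(ds)))
  expect_equal(unname(cr$se), c(sqrt(sum(si^2)), sqrt(sum(ss^2))))
})

test_that("trajectories handle zero gradients, modes and missing years", {
  G <- matrix(c(4, 0.05, 0.05, 0.02), 2)
  seG <- matrix(0.2, 2, 2)
  env <- data.frame(year = 2001:2010, cue_temp = rnorm(10, 8))
  grads <- data.frame(year = 2004:2010, beta_z = 0, se = 0.01)
  pr <- data.frame(year = 2001:2011, p_recr = 0.4)
  tr <- predict_trajectory(G, seG, grads, env, pr, baseline_period = c(2001, 2003))
  expect_equal(unname(tr$cumulative$cum), c(0, 0))
  # uncorrected mode equals the raw breeder's equation per year
  grads$beta_z <- -0.05
  tr2 <- predict_trajectory(G, seG, grads, env, pr, c(2001, 2003),
                            corrected = FALSE)
  y <- tr2$by_year[tr2$by_year$year == 2005, ]
  expect_equal(c(y$d_int, y$d_slope),
               unname(annual_response(G, y$x_j, -0.05)), tolerance = 1e-12)
  # corrected mode is 0.5 * p_recr times the uncorrected one
  tr3 <- predict_trajectory(G, seG, grads, env, pr, c(2001, 2003))
  expect_equal(tr3$by_year$d_int, tr2$by_year$d_int * 0.5 * 0.4,
               tolerance = 1e-12)
  # a missing gradient year is flagged and skipped
  tr4 <- predict_trajectory(G, seG, grads[grads$year != 2006, ], env, pr,
                            c(2001, 2003))
  expect_equal(tr4$by_year$flag[tr4$by_year$year == 2006], "no_gradient")
  expect_error(predict_trajectory(G, seG, grads, env, pr, c(2001, 2010)),
               "nothing to predict")
})
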