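make_daily <- function(years, doys = 32:151, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(years, function(y)
    data.frame(year = y, doy = doys,
               temperature = rnorm(length(doys), 8, 3))))
}

test_that("window means are plain arithmetic means with gap checking", {
  s <- data.frame(year = 2000, doy = 60:120, temperature = 10)
  expect_equal(window_mean(s, 70, 110, 2000), 10)
  s2 <- data.frame(year = 2000, doy = c(70, 71), temperature = c(8, 12))
  expect_equal(window_mean(s2, 70, 71, 2000), 10)
  expect_error(window_mean(s2, 70, 72, 2000), "missing day")
  s3 <- make_daily(2001)
  inwin <- s3$doy >= 80 & s3$doy <= 100
  expect_equal(window_mean(s3, 80, 100, 2001),
               sum(s3$temperature[inwin]) / sum(inwin))
})

test_that("a planted cue window is found with r-squared one", {
  years <- 1981:2000
  daily <- make_daily(years, seed = 3)
  means <- vapply(years, function(y) window_mean(daily, 70, 110, y), 0)
  resp <- data.frame(year = years, response = 40 - 3 * means)
  bw <- find_best_window(daily, resp, start_range = c(60, 80),
                         end_range = c(100, 120), min_length = 10)
  expect_equal(bw$start_doy, 70)
  expect_equal(bw$end_doy, 110)
  expect_equal(bw$r_squared, 1, tolerance = 1e-10)
  expect_equal(bw$slope, -3, tolerance = 1e-8)
})

test_that("the grid maximum equals a brute-force recomputation", {
  years <- 1961:2000
  daily <- make_daily(years, seed = 4)
  set.seed(5)
  resp <- data.frame(year = years, response = rnorm(40)) # pure noise
  bw <- find_best_window(daily, resp, start_range = c(65, 75),
                         end_range = c(95, 105), min_length = 7)
  # independent brute force over the same grid
  brute <- -Inf
  for (st in 65:75) for (en in 95:105) {
    if (en - st + 1 < 7) next
    m <- vapply(years, function(y) window_mean(daily, st, en, y), 0)
    brute <- max(brute, cor(m, resp$response)^2)
  }
  expect_equal(bw$r_squared, brute, tolerance = 1e-12)
  expect_true(all(bw$r_squared >= bw$grid$r_squared - 1e-12))
  expect_lt(bw$r_squared, 0.5) # noise response: weak best correlation
})

test_that("contract errors are raised for bad inputs", {
  years <- 1991:2000
  daily <- make_daily(years, seed = 6)
  resp <- data.frame(year = years, response = rnorm(10))
  expect_error(find_best_window(daily, resp, start_range = c(70, 72),
                                end_range = c(74, 76), min_length = 30),
               "empty candidate grid")
  expect_error(find_best_window(daily, data.frame(year = years, response = 1),
                                start_range = c(60, 70), end_range = c(90, 100)),
               "response constant")
  expect_error(find_best_window(daily, resp[1:3, ], start_range = c(60, 70),
                                end_range = c(90, 100)), "at least 5 years")
})
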