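test_that("identical slopes give F of zero and a parallel verdict", {
  d <- linear_parallelism_data(std_slope = -20, pool_slope = -20)
  r <- parallelism_test(d$standards, d$pool)
  expect_equal(r$standard_slope, r$pool_slope, tolerance = 1e-8)
  expect_lt(r$f_statistic, 1e-8)
  expect_true(r$parallel)
  expect_equal(r$df[2], 14 - 4)   # two-line model on 7 + 7 points
})

test_that("a pool on the same dose-response curve reads as parallel", {
  # pool = exact dose-scaled copy of the standards along one 4PL curve:
  # the 1:8..neat dilutions of a 1248 pg/mL pool land on the same doses
  p <- list(a = 100, b = 1, c = 500, d = 0)
  conc <- 156 * 2^(3:0)
  dil <- c(8, 4, 2, 1)
  std <- data.frame(conc = conc, pb = predict_4pl(conc, p))
  pool <- data.frame(dilution = dil, pb = predict_4pl(1248 / dil, p))
  r <- parallelism_test(std, pool)
  expect_true(r$parallel)
  expect_lt(abs(r$standard_slope - r$pool_slope), 1e-8)
  expect_lt(r$f_statistic, 1e-8)
})

test_that("a doubled pool slope is rejected in over 90% of noisy replicates", {
  set.seed(55)
  reject <- logical(500)
  for (i in seq_along(reject)) {
    d <- linear_parallelism_data(std_slope = -20, pool_slope = -40,
                                 noise = 1)
    reject[i] <- !parallelism_test(d$standards, d$pool)$parallel
  }
  expect_gt(mean(reject), 0.90)
})

test_that("F statistic is invariant to which series is called standard", {
  set.seed(56)
  d <- linear_parallelism_data(std_slope = -20, pool_slope = -30,
                               noise = 1)
  r1 <- parallelism_test(d$standards, d$pool)
  # relabel: feed the pool as "standards" (dose = 1/dilution) and the
  # standards as "pool" (dilution = 1/conc)
  r2 <- parallelism_test(
    data.frame(conc = 1 / d$pool$dilution, pb = d$pool$pb),
    data.frame(dilution = 1 / d$standards$conc, pb = d$standards$pb))
  expect_equal(r1$f_statistic, r2$f_statistic, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("50% binding is interpolated between the bracketing dilutions", {
  # %B 55 at 1:4 and 45 at 1:8 bracket 50%; log-dose interpolation lands
  # between, at the conventionally quoted 1:6
  b50 <- fgmassay:::interpolate_binding50(c(2, 4, 8, 16),
                                          c(70, 55, 45, 30))
  expect_gt(b50, 4); expect_lt(b50, 8)
  expect_equal(round(b50), 6)

  # all points on one side of 50%: unavailable
  expect_true(is.na(fgmassay:::interpolate_binding50(c(1, 2, 4),
                                                     c(90, 80, 70))))
  d <- linear_parallelism_data()
  r <- parallelism_test(d$standards, d$pool)
  expect_true(is.finite(r$binding50_dilution))
})

test_that("working dilution takes the matrix-interference floor into account", {
  expect_equal(choose_working_dilution(6, floor = 10), 10)
  expect_equal(choose_working_dilution(30, floor = 10), 30)
  expect_equal(choose_working_dilution(10, floor = 10), 10)
  r <- structure(list(binding50_dilution = 6), class = "parallelism_result")
  expect_equal(choose_working_dilution(r, floor = 10), 10)
  r$binding50_dilution <- NA_real_
  expect_error(choose_working_dilution(r), "no 50%")
})

test_that("accuracy regression applies the r2 and slope acceptance band", {
  expected <- 156 * 2^(6:0) / 1000
  # identity: accepted
  r <- accuracy_test(expected, expected)
  expect_equal(r$slope, 1); expect_equal(r$r_squared, 1)
  expect_true(r$accepted)
  # proportional bias of 0.5: perfect fit but outside the slope band
  r2 <- accuracy_test(expected, 0.5 * expected)
  expect_equal(r2$slope, 0.5); expect_equal(r2$r_squared, 1)
  expect_false(r2$accepted)
  # mild noise: still accepted
  set.seed(77)
  obs <- expected + rnorm(7, 0, 0.02 * diff(range(expected)))
  expect_true(accuracy_test(expected, obs)$accepted)

  expect_error(accuracy_test(rep(1, 4), c(1, 2, 3, 4)), "zero variance")
  expect_error(accuracy_test(1:2, 1:2), "length >= 3")
})

test_that("accuracy slope and r2 match the closed-form OLS oracle", {
  set.seed(78)
  for (i in 1:20) {
    x <- runif(8, 0, 10)
    y <- 2 + 0.9 * x + rnorm(8)
    r <- accuracy_test(x, y)
    o <- ols_oracle(x, y)
    expect_equal(r$slope, o$slope, tolerance = 1e-10)
    expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(r$r_squared, o$r_squared, tolerance = 1e-10)
  }
})
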