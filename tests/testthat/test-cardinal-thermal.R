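test_that("peak curve evaluates correctly and respects its domain", {
  expect_equal(peak_function(29, a = 0.3, b = 5, c = 29, d = 35),
               0.3 * exp(-1 / 6))
  # the rate collapses to zero approaching the descending intercept
  expect_lt(peak_function(34.999, a = 0.3, b = 5, c = 29, d = 35), 1e-8)
  expect_error(peak_function(35, a = 0.3, b = 5, c = 29, d = 35),
               "undefined")
  expect_error(peak_function(36, a = 0.3, b = 5, c = 29, d = 35),
               "undefined")
})

test_that("peak fit recovers exact parameters from noiseless rates", {
  temps <- c(11, 14, 17, 21, 23, 25, 28, 31, 33)
  gr <- oracle_peak_curve(temps, 0.3, 5, 29, 35)
  fit <- fit_peak(temps, gr)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.3, 5, 29, 35), tolerance = 1e-4)
  expect_gt(fit$r2, 1 - 1e-8)
  expect_false(fit$descending_limb_missing)
})

test_that("peak fit rejects under-determined or flat input and flags boundary maxima", {
  expect_error(fit_peak(c(20, 25, 30), c(0.1, 0.2, 0.1)), "at least 5")
  expect_error(fit_peak(11:20, rep(0.2, 10)), "all rates equal")
  monotone <- fit_peak(seq(12, 32, length.out = 9),
                       oracle_peak_curve(seq(12, 32, length.out = 9),
                                         0.3, 5, 33, 40))
  expect_true(monotone$descending_limb_missing)
})

test_that("inflection points match a brute-force scan and scale invariance holds", {
  fit <- peak_fit(0.3, 5, 29, 35, t_min = 11)
  infl <- inflection_points(fit)
  orc <- oracle_tangent_cardinals(0.3, 5, 29, 35, lower = 6)
  expect_lt(abs(infl$x_max - orc$x_max), 5e-3)
  expect_lt(abs(infl$x_min - orc$x_min), 5e-3)
  # the curve's interior maximum lies between the inflections with zero slope
  pk_x <- optimize(function(x) peak_value(fit, x),
                   c(infl$x_max, infl$x_min), maximum = TRUE)$maximum
  h <- 1e-5
  slope_at_peak <- (peak_value(fit, pk_x + h) - peak_value(fit, pk_x - h)) /
    (2 * h)
  expect_lt(abs(slope_at_peak), 1e-5)
  expect_gt(pk_x, infl$x_max)
  expect_lt(pk_x, infl$x_min)
  # vertical scaling does not move the inflection temperatures
  tall <- peak_fit(3, 5, 29, 35, t_min = 11)
  infl10 <- inflection_points(tall)
  expect_equal(infl10$x_max, infl$x_max, tolerance = 1e-5)
  expect_equal(infl10$x_min, infl$x_min, tolerance = 1e-5)
})

test_that("tangent extrapolation reproduces the grid oracle and its geometry", {
  fit <- peak_fit(0.3, 5, 29, 35, t_min = 11)
  card <- tangent_cardinals(fit)
  orc <- oracle_tangent_cardinals(0.3, 5, 29, 35, lower = 6)
  expect_lt(abs(card$Tb - orc$Tb), 0.05)
  expect_lt(abs(card$Tc - orc$Tc), 0.05)
  expect_lt(abs(card$Ttsub - orc$Ttsub), 0.5)
  expect_lt(abs(card$Ttsup - orc$Ttsup), 0.5)
  # tangents extend beyond the inflections on each side
  expect_lt(card$Tb, card$x_max)
  expect_gt(card$Tc, card$x_min)
  expect_gt(card$slope_max, 0)
  expect_lt(card$slope_min, 0)
})

test_that("cardinal ordering and vertical-scale laws hold over random peak curves", {
  set.seed(7)
  for (k in 1:20) {
    a <- runif(1, 0.05, 0.5); b <- runif(1, 1, 10)
    c <- runif(1, 20, 32); d <- c + runif(1, 2, 10)
    lower <- c * (1 - 2 / sqrt(2 * b)) - 1
    card <- tangent_cardinals(peak_fit(a, b, c, d), lower = lower)
    expect_true(card$Tb < card$x_max)
    expect_true(card$x_max < c)
    expect_true(c < card$x_min)
    expect_true(card$x_min < card$Tc)
    expect_true(card$Tc < d)
    # scaling the rate axis by k leaves Tb/Tc fixed, divides thermal times
    k10 <- tangent_cardinals(peak_fit(10 * a, b, c, d), lower = lower)
    expect_equal(k10$Tb, card$Tb, tolerance = 1e-6)
    expect_equal(k10$Tc, card$Tc, tolerance = 1e-6)
    expect_equal(k10$Ttsub, card$Ttsub / 10, tolerance = 1e-6)
    expect_equal(k10$Ttsup, card$Ttsup / 10, tolerance = 1e-6)
  }
})

test_that("percentile-thermal time regression returns slope in %/degC day", {
  tt <- c(10, 20, 30, 40)
  reg <- suppressWarnings(
    percentile_tt_regression(2 * tt - 10, tt, range = "sub"))
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, -10)
  expect_equal(reg$r2, 1)
  expect_error(percentile_tt_regression(c(10, 20, 30), rep(5, 3), "sub"),
               "constant")
  expect_error(percentile_tt_regression(c(10, 20), c(1, 2), "sub"),
               "at least 3")
})

test_that("the pipeline recovers the generating percentile-vs-thermal-time slope", {
  slopes <- sapply(1:3, function(s) {
    cfg <- simulation_config(rng_seed = s)
    res <- analyze_thermal_time(simulate_population(cfg, elevation = 2040))
    sub <- res$tt_regressions[res$tt_regressions$range == "sub", ]
    expect_gt(nrow(sub), 0)
    mean(sub$slope)
  })
  expect_lt(abs(mean(slopes) / simulation_config()$sub_slope - 1), 0.15)
})

test_that("cardinal aggregation yields one summarised row per lot cell", {
  card <- expand.grid(elevation = c(1260, 2500), percentile = c(20, 50),
                      replicate = 1:3)
  card$Tb_C <- 10.5
  card$Tc_C <- 34.8 + 0.05 * card$replicate
  card$Ttsub_Cday <- 60 + card$percentile / 10
  card$Ttsup_Cday <- 6
  agg <- suppressWarnings(aggregate_cardinals(card))  # exact toy data
  expect_equal(nrow(agg), 4L)
  expect_equal(agg$n, rep(3L, 4))
  expect_true(all(agg$Tb_C_mean == 10.5))
  expect_true(all(agg$Tb_C_sd == 0))
  expect_true(all(agg$Ttsub_Cday_sd == 0))
})
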