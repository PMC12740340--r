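test_that("logistic fit recovers exact parameters on noiseless data", {
  grid <- expand.grid(a = c(60, 90), b = c(5, 15, 40), c = c(0.3, 0.6))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    dat <- make_logistic_counts(p$a, p$b, p$c)
    fit <- fit_sigmoid(dat$day, dat$count, dat$n_seeds)
    expect_true(fit$converged)
    expect_equal(fit$a, p$a, tolerance = 1e-6)
    expect_equal(fit$b, p$b, tolerance = 1e-6)
    expect_equal(fit$c, p$c, tolerance = 1e-6)
    expect_gt(fit$r2, 1 - 1e-10)
  }
})

test_that("empty and saturated courses are flagged, not fitted", {
  expect_error(fit_sigmoid(1:10, rep(0, 10), 50),
               class = "thermogerm_no_germination")
  sat <- fit_sigmoid(1:10, rep(50, 10), 50)
  expect_true(sat$degenerate)
  expect_equal(sat$a, 100)
  expect_false(sat$converged)
  expect_error(fit_sigmoid(1:3, c(0, 1, 2), 50), "4 distinct")
  expect_error(fit_sigmoid(1:5, c(0, 2, 1, 3, 4), 50), "nondecreasing")
})

test_that("time to percentile inverts the logistic in closed form", {
  fit <- list(a = 100, b = 20, c = 0.5)
  expect_equal(time_to_percentile(fit, 50), log(20) / 0.5)
  expect_equal(germination_rate(time_to_percentile(fit, 50)), 0.16690,
               tolerance = 1e-4)
  expect_equal(time_to_percentile(fit, 100 / 21), 0)  # the intercept a/(1+b)
  expect_error(time_to_percentile(fit, 100),
               class = "thermogerm_percentile_unreachable")
  expect_error(time_to_percentile(fit, 120),
               class = "thermogerm_percentile_unreachable")
  expect_error(time_to_percentile(fit, 0), "positive")
  expect_error(time_to_percentile(fit, 2), "negative time")
})

test_that("sigmoid inversion round-trips and is monotone", {
  set.seed(19)
  for (k in 1:25) {
    fit <- list(a = runif(1, 40, 100), b = runif(1, 2, 50),
                c = runif(1, 0.1, 1.5))
    y <- runif(1, fit$a / (1 + fit$b) + 1e-6, fit$a - 1e-6)
    t <- time_to_percentile(fit, y)
    expect_equal(sigmoid_value(fit, t), y, tolerance = 1e-9)
    # strictly increasing in y
    y2 <- min(y * 1.05, fit$a - 1e-9)
    expect_gt(time_to_percentile(fit, y2), t)
    # strictly decreasing in c
    faster <- fit; faster$c <- fit$c * 1.5
    if (t > 0) expect_lt(time_to_percentile(faster, y), t)
  }
})

test_that("percentages are scaled to the lot-wide observed maximum", {
  toy <- function(finals) {
    # one seed lot, 3 census days; `finals` indexed [temperature][replicate]
    rows <- list()
    for (i in seq_along(finals)) for (j in seq_along(finals[[i]])) {
      fin <- finals[[i]][j]
      rows[[length(rows) + 1L]] <- data.frame(
        elevation = 0, temperature_C = 20 + i, replicate = j, n_seeds = 200,
        day = 1:3, cumulative_germinated = c(0, fin, fin) * 2)
    }
    do.call(rbind, rows)
  }
  sc <- scale_to_max(toy(list(c(91.5, 80), c(85, 70))))
  expect_equal(sc$max_observed_pct, 91.5)
  # scaled percentile 50 corresponds to raw 45.75%
  expect_equal(50 / sc$factor, 45.75)
  sc100 <- scale_to_max(toy(list(c(100, 90), c(95, 88))))
  expect_equal(sc100$factor, 1)
  # floor-to-decile rule on the minimum scaled replicate-mean final
  sc68 <- scale_to_max(toy(list(c(100, 100), c(68, 68))))
  expect_equal(sc68$percentiles, seq(10, 60, 10))
  expect_error(scale_to_max(toy(list(c(0, 0)))),
               class = "thermogerm_no_germination")
})

test_that("lag time is the first census with germination and shortens when warm", {
  expect_equal(lag_time(1:4, c(0, 0, 3, 5)), 3)
  expect_true(is.na(lag_time(1:4, rep(0, 4))))
  cfg <- simulation_config(temperatures = c(17, 28), viability = 1,
                           n_seeds = 200, n_replicates = 1, rng_seed = 8)
  tc <- simulate_population(cfg)
  lag_of <- function(temp) {
    d <- tc[tc$temperature_C == temp, ]
    lag_time(d$day, d$cumulative_germinated)
  }
  expect_lte(lag_of(28), lag_of(17))
})

test_that("arcsine square-root transform is correct and increasing", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(100), pi / 2)
  expect_equal(arcsine_transform(50), pi / 4)
  p <- seq(0, 100, by = 5)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(-1), "\\[0, 100\\]")
  expect_error(arcsine_transform(101), "\\[0, 100\\]")
})

test_that("group comparison reproduces the hand-computed ANOVA and letters", {
  cmp <- compare_groups(c(1, 2, 3, 7, 8, 9), rep(c("g1", "g2"), each = 3))
  expect_equal(cmp$f_value, 54)                 # SSB 54, MSW 1, df (1, 4)
  expect_equal(cmp$df, c(1, 4))
  expect_false(cmp$letters[["g1"]] == cmp$letters[["g2"]])
  # identical groups share a letter
  same <- compare_groups(c(5, 6, 5, 6), c("a", "a", "b", "b"))
  expect_equal(unname(same$letters["a"]), unname(same$letters["b"]))
  # a clearly separated mean gets its own letter
  set.seed(42)
  vals <- c(rnorm(6, 0, 0.1), rnorm(6, 0.2, 0.1), rnorm(6, 30, 0.1))
  grp <- rep(c("lo", "mid", "far"), each = 6)
  cl <- compare_groups(vals, grp)$letters
  expect_false(cl[["far"]] %in% cl[c("lo", "mid")])
  # zero-variance degenerate input collapses to a single letter
  flat <- compare_groups(rep(2, 6), rep(c("x", "y"), each = 3))
  expect_true(all(flat$letters == "a"))
})
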