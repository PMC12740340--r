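test_that("true germination rate follows the thermal-time relations", {
  cfg <- simulation_config(true_Tb = 10.5, true_To = 29.5, true_Tc = 35,
                           theta_sub50 = 60)
  expect_equal(true_rate(50, cfg$true_Tb, cfg), 0)
  expect_equal(true_rate(50, cfg$true_Tc, cfg), 0)
  expect_equal(true_rate(50, 22.5, cfg), 0.2)            # (22.5-10.5)/60
  # linear in T on each branch
  expect_equal(true_rate(50, 16.5, cfg), 0.1)
  # supra branch uses theta_sup
  expect_equal(true_rate(50, 31, cfg), (35 - 31) / cfg$theta_sup50)
  # percentile mapping is the inverse linear fit
  expect_equal(true_rate(75, 22.5, cfg), 12 / (60 + 25 / cfg$sub_slope))
  expect_error(true_rate(0, 20, cfg), "strictly between")
  expect_error(true_rate(100, 20, cfg), "strictly between")
  expect_error(true_rate(NaN, 20, cfg), "finite")
  expect_error(true_rate(50, Inf, cfg), "finite")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(true_Tb = 30, true_To = 20), "true_Tb <")
  expect_error(simulation_config(theta_sub50 = -1), "positive")
  expect_error(simulation_config(viability = 0), "viability")
  expect_error(simulation_config(viability = 1.2), "viability")
  expect_error(simulation_config(census_interval = 0), "census_interval")
})

test_that("simulated time courses are cumulative, bounded and seeded-reproducible", {
  cfg <- small_study_config(seed = 11)
  tc <- simulate_population(cfg, elevation = 1660)
  expect_setequal(unique(tc$temperature_C), cfg$temperatures)
  for (grp in split(tc, interaction(tc$temperature_C, tc$replicate))) {
    expect_true(all(diff(grp[order(grp$day), "cumulative_germinated"]) >= 0))
    expect_true(all(grp$cumulative_germinated >= 0 &
                      grp$cumulative_germinated <= cfg$n_seeds))
  }
  expect_identical(tc, simulate_population(cfg, elevation = 1660))
  # below the base temperature nothing ever germinates
  cold <- simulation_config(temperatures = 8.5, rng_seed = 1)
  expect_true(all(simulate_population(cold)$cumulative_germinated == 0))
  # fully viable seeds all finish at the optimum
  full <- simulation_config(temperatures = 29.5, viability = 1,
                            max_days = 60, rng_seed = 2, n_replicates = 2)
  fin <- simulate_population(full)
  expect_true(all(tapply(fin$cumulative_germinated, fin$replicate, max) ==
                    full$n_seeds))
})

test_that("final germination fraction is binomial in the configured viability", {
  cfg <- simulation_config(temperatures = 29.5, viability = 0.9,
                           n_seeds = 50, n_replicates = 5, max_days = 60,
                           rng_seed = 33)
  tc <- simulate_population(cfg)
  finals <- tapply(tc$cumulative_germinated, tc$replicate, max)
  p_hat <- mean(finals) / cfg$n_seeds
  se <- sqrt(0.9 * 0.1 / (5 * 50))
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("median germination time converges to the thermal-time prediction", {
  cfg <- simulation_config(temperatures = 21, viability = 1, n_seeds = 4000,
                           n_replicates = 1, census_interval = 0.01,
                           max_days = 60, rng_seed = 5)
  tc <- simulate_population(cfg)
  counts <- tc$cumulative_germinated
  med_day <- tc$day[which(counts >= cfg$n_seeds / 2)[1L]]
  expect_lt(abs(med_day - 60 / (21 - 10.5)), 0.15)
})

test_that("simulated soil traces have the configured geometry", {
  flat <- simulate_soil_trace(20, 0, 0, days = 2, interval = 30)
  expect_true(all(flat$temperature_C == 20))
  tr <- simulate_soil_trace(20, 8, 0, days = 7, interval = 30)
  expect_equal(nrow(tr), 336)
  expect_equal(max(tr$temperature_C), 28)      # peak sampled at 14:00
  peak_minutes <- tr$timestamp_minutes[tr$temperature_C == 28] %% 1440
  expect_true(all(peak_minutes == 840))
  noisy1 <- simulate_soil_trace(20, 8, 1, days = 2, interval = 10,
                                rng_seed = 4)
  noisy2 <- simulate_soil_trace(20, 8, 1, days = 2, interval = 10,
                                rng_seed = 4)
  expect_identical(noisy1, noisy2)
  expect_error(simulate_soil_trace(20, -1, 0, days = 1), "non-negative")
  expect_error(simulate_soil_trace(20, 1, 0, days = 0), "positive")
  expect_error(simulate_soil_trace(20, 1, 0, days = 1, interval = 7),
               "divide")
})

test_that("fatty-acid reference table has the published layout and values", {
  fa <- fatty_acid_table()
  expect_equal(dim(fa), c(5L, 6L))
  expect_equal(fa$elevation_m, c(1260, 1660, 2040, 2345, 2500))
  expect_equal(fa$linoleic_mg_g[fa$elevation_m == 2500], 272.063)
  expect_equal(fa$palmitic_mg_g[fa$elevation_m == 1660], 14.800)
})
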