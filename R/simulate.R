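#' Configuration of the germination simulator
#'
#' Bundles the parameters of the population-threshold generating model
#' used by [simulate_population()]. Each seed carries a percentile
#' threshold `g` drawn uniformly on (0, 100); its thermal time is a
#' linear function of `g` (the inverse of the percentile-versus-thermal
#' time regressions the analysis fits), and its germination time at
#' incubation temperature `T` follows the thermal-time relations
#' \eqn{t = \theta_{sub}(g) / (T - T_b)} below the optimum and
#' \eqn{t = \theta_{sup}(g) / (T_c - T)} above it.
#'
#' Defaults describe a seed lot of a thermophilic pioneer tree incubated
#' on a laboratory thermogradient: nine constant temperatures between 11
#' and 33 degC, five replicates of 50 seeds each, daily censusing for 30
#' days, base temperature 10.5 degC, ceiling 35 degC, 50th-percentile
#' suboptimal thermal time 60 degC day, and 90 percent viability.
#'
#' @param true_Tb,true_To,true_Tc Base, optimal and ceiling temperatures
#'   of the generating model (degC); must satisfy `true_Tb < true_To <
#'   true_Tc`.
#' @param theta_sub50 Suboptimal thermal time of the 50th percentile
#'   (degC day), positive.
#' @param sub_slope Slope of the percentile-versus-suboptimal-thermal-time
#'   line (percent per degC day), positive: percentile `g` has
#'   `theta_sub50 + (g - 50) / sub_slope`.
#' @param theta_sup50 Supraoptimal thermal time of the 50th percentile
#'   (degC day), positive. The default keeps the generating rate law
#'   continuous at `true_To`.
#' @param sup_slope Slope of the percentile-versus-supraoptimal-thermal-time
#'   line (percent per degC day), positive: percentile `g` has
#'   `theta_sup50 - (g - 50) / sup_slope` (later percentiles germinate
#'   faster relative to the ceiling).
#' @param viability Probability that a seed is viable, in (0, 1].
#' @param n_seeds Seeds sown per replicate.
#' @param n_replicates Replicates per temperature.
#' @param temperatures Incubation temperatures (degC).
#' @param census_interval Days between censuses (default daily).
#' @param max_days Length of the recording period (days).
#' @param lag Fixed physiological lag added to every germination time
#'   (days); default 0.
#' @param rng_seed Integer seed for the simulation stream, or `NULL`.
#'
#' @return A list of class `simulation_config`.
#' @seealso [simulate_population()], [true_rate()]
#' @examples
#' cfg <- simulation_config(n_seeds = 20, n_replicates = 2)
#' cfg$true_Tb
#' @export
simulation_config <- function(true_Tb = 10.5,
                              true_To = 29.5,
                              true_Tc = 35,
                              theta_sub50 = 60,
                              sub_slope = 2.5,
                              theta_sup50 = 17.4,
                              sup_slope = 15,
                              viability = 0.9,
                              n_seeds = 50,
                              n_replicates = 5,
                              temperatures = c(11, 14, 17, 21, 23, 25, 28, 31, 33),
                              census_interval = 1,
                              max_days = 30,
                              lag = 0,
                              rng_seed = NULL) {
  cfg <- list(true_Tb = true_Tb, true_To = true_To, true_Tc = true_Tc,
              theta_sub50 = theta_sub50, sub_slope = sub_slope,
              theta_sup50 = theta_sup50, sup_slope = sup_slope,
              viability = viability, n_seeds = n_seeds,
              n_replicates = n_replicates, temperatures = temperatures,
              census_interval = census_interval, max_days = max_days,
              lag = lag, rng_seed = rng_seed)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(
    num1(cfg$true_Tb), num1(cfg$true_To), num1(cfg$true_Tc),
    num1(cfg$theta_sub50), num1(cfg$theta_sup50),
    num1(cfg$sub_slope), num1(cfg$sup_slope),
    num1(cfg$viability), num1(cfg$lag),
    is.numeric(cfg$temperatures), length(cfg$temperatures) >= 1L,
    all(is.finite(cfg$temperatures))
  )
  if (!(cfg$true_Tb < cfg$true_To && cfg$true_To < cfg$true_Tc))
    stop("cardinal temperatures must satisfy true_Tb < true_To < true_Tc")
  if (cfg$theta_sub50 <= 0 || cfg$theta_sup50 <= 0)
    stop("theta_sub50 and theta_sup50 must be positive")
  if (cfg$sub_slope <= 0 || cfg$sup_slope <= 0)
    stop("sub_slope and sup_slope must be positive")
  if (cfg$viability <= 0 || cfg$viability > 1)
    stop("viability must be in (0, 1]")
  if (cfg$n_seeds < 1) stop("n_seeds must be >= 1")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (cfg$census_interval <= 0) stop("census_interval must be positive")
  if (cfg$max_days <= 0) stop("max_days must be positive")
  if (cfg$lag < 0) stop("lag must be non-negative")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Germination simulation configuration\n")
  cat(sprintf("  cardinal temperatures: Tb %.2f, To %.2f, Tc %.2f degC\n",
              x$true_Tb, x$true_To, x$true_Tc))
  cat(sprintf("  theta50: sub %.1f, sup %.1f degC day (slopes %.2f / %.2f %%/degC day)\n",
              x$theta_sub50, x$theta_sup50, x$sub_slope, x$sup_slope))
  cat(sprintf("  design: %d temperatures x %d replicates x %d seeds, viability %.2f\n",
              length(x$temperatures), x$n_replicates, x$n_seeds, x$viability))
  cat(sprintf("  census every %g d for %g d\n", x$census_interval, x$max_days))
  invisible(x)
}

# percentile -> thermal time mappings of the generating model
theta_sub_of <- function(g, cfg) cfg$theta_sub50 + (g - 50) / cfg$sub_slope
theta_sup_of <- function(g, cfg) cfg$theta_sup50 - (g - 50) / cfg$sup_slope

#' True germination rate of a percentile cohort
#'
#' Evaluates the generating rate law at percentile `g` and temperature
#' `temp`: \eqn{(T - T_b)/\theta_{sub}(g)} at and below the optimum,
#' \eqn{(T_c - T)/\theta_{sup}(g)} above it, floored at zero outside the
#' permissive range. The sub- and supraoptimal branches are independent;
#' continuity at the optimum holds only if the two theta mappings agree
#' there (the default configuration arranges this for the median seed).
#'
#' @param g Percentile in (0, 100); vectorised.
#' @param temp Temperature (degC); vectorised (recycled against `g`).
#' @param cfg A [simulation_config()].
#' @return Germination rate(s) in 1/day.
#' @examples
#' cfg <- simulation_config()
#' true_rate(50, 22.5, cfg)  # (22.5 - 10.5) / 60 = 0.2
#' @export
true_rate <- function(g, temp, cfg) {
  validate_simulation_config(cfg)
  if (!is.numeric(g) || !all(is.finite(g)))
    stop("percentile g must be finite numeric")
  if (any(g <= 0 | g >= 100))
    stop("percentile g must lie strictly between 0 and 100")
  if (!is.numeric(temp) || !all(is.finite(temp)))
    stop("temperature must be finite numeric")
  n <- max(length(g), length(temp))
  g <- rep_len(g, n); temp <- rep_len(temp, n)
  th_sub <- theta_sub_of(g, cfg)
  th_sup <- theta_sup_of(g, cfg)
  if (any(th_sub <= 0))
    stop("theta_sub(g) must be positive for every requested percentile")
  if (any(th_sup <= 0))
    stop("theta_sup(g) must be positive for every requested percentile")
  ifelse(temp <= cfg$true_To,
         pmax(0, temp - cfg$true_Tb) / th_sub,
         pmax(0, cfg$true_Tc - temp) / th_sup)
}

#' Simulate germination time courses for one seed lot
#'
#' Draws, for every temperature and replicate of the configuration,
#' `n_seeds` independent seeds: each is viable with probability
#' `viability` and carries a percentile threshold uniform on (0, 100).
#' A viable seed's continuous germination time is `lag + 1/true_rate`;
#' it is recorded at the first census on or after that time. Seeds with
#' zero rate, or whose time exceeds `max_days`, never germinate.
#'
#' One shared RNG stream is used, seeded from `cfg$rng_seed` when set,
#' with temperatures and replicates drawn in deterministic order, so a
#' seeded run is exactly reproducible.
#'
#' @param cfg A [simulation_config()].
#' @param elevation Elevation label (m a.s.l.) attached to the output.
#' @return A data frame in long census format with columns `elevation`,
#'   `temperature_C`, `replicate`, `n_seeds`, `day`,
#'   `cumulative_germinated`; cumulative counts are nondecreasing within
#'   each (temperature, replicate).
#' @examples
#' cfg <- simulation_config(n_seeds = 25, n_replicates = 2, rng_seed = 1)
#' tc <- simulate_population(cfg, elevation = 2345)
#' head(tc)
#' @export
simulate_population <- function(cfg, elevation = 0) {
  validate_simulation_config(cfg)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  census <- seq(cfg$census_interval, cfg$max_days, by = cfg$census_interval)
  out <- vector("list", length(cfg$temperatures) * cfg$n_replicates)
  k <- 0L
  for (temp in cfg$temperatures) {
    for (rep_i in seq_len(cfg$n_replicates)) {
      viable <- runif(cfg$n_seeds) < cfg$viability
      g <- runif(cfg$n_seeds, 0, 100)
      rate <- true_rate(g, temp, cfg)
      t_germ <- ifelse(viable & rate > 0, cfg$lag + 1 / rate, Inf)
      # census day containing the continuous time (daily recording)
      day_germ <- ceiling(t_germ / cfg$census_interval) * cfg$census_interval
      day_germ[day_germ < census[1L]] <- census[1L]
      counts <- vapply(census, function(d) sum(day_germ <= d), integer(1))
      k <- k + 1L
      out[[k]] <- data.frame(
        elevation = elevation,
        temperature_C = temp,
        replicate = rep_i,
        n_seeds = cfg$n_seeds,
        day = census,
        cumulative_germinated = counts
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate a diurnal soil-temperature logger trace
#'
#' Generates an equally spaced temperature record with a 24 h sinusoidal
#' cycle peaking at 14:00 (the afternoon soil-temperature maximum of a
#' shallow buried logger) plus independent Gaussian noise.
#'
#' @param mean Mean temperature (degC).
#' @param amplitude Half peak-to-trough amplitude (degC), non-negative.
#' @param noise_sd Standard deviation of the additive noise (degC).
#' @param days Number of whole days recorded, positive.
#' @param interval Minutes between readings; must divide 1440.
#' @param rng_seed Integer seed or `NULL`.
#' @return A data frame of class `soil_trace` with columns
#'   `timestamp_minutes` (minutes since trace start, starting at 0) and
#'   `temperature_C`, and attribute `interval` (minutes).
#' @examples
#' tr <- simulate_soil_trace(20, 8, 0, days = 7, interval = 30)
#' nrow(tr)   # 336 readings
#' max(tr$temperature_C)
#' @export
simulate_soil_trace <- function(mean, amplitude, noise_sd = 0, days,
                                interval = 30, rng_seed = NULL) {
  stopifnot(is.finite(mean), is.finite(amplitude), is.finite(noise_sd))
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (days <= 0) stop("days must be positive")
  if (interval <= 0) stop("interval must be positive")
  if (1440 %% interval != 0) stop("interval must divide 1440 minutes")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tmin <- seq(0, days * 1440 - interval, by = interval)
  # cosine peaking at minute 840 of the day (14:00)
  temp <- mean + amplitude * cos(2 * pi * (tmin %% 1440 - 840) / 1440)
  if (noise_sd > 0) temp <- temp + rnorm(length(tmin), 0, noise_sd)
  trace <- data.frame(timestamp_minutes = tmin, temperature_C = temp)
  attr(trace, "interval") <- interval
  class(trace) <- c("soil_trace", "data.frame")
  trace
}

#' Reference fatty-acid profiles of the five elevational seed lots
#'
#' Concentrations (mg per g fresh seed) of the five fatty acids found in
#' the seed oil of five elevational populations (1260-2500 m a.s.l.) of a
#' neotropical pioneer tree. Palmitic,
#' stearic and nonadecilic acids are saturated; linoleic and oleic are
#' unsaturated.
#'
#' @return A data frame with columns `elevation_m`, `palmitic_mg_g`,
#'   `linoleic_mg_g`, `oleic_mg_g`, `stearic_mg_g`, `nonadecilic_mg_g`;
#'   one row per elevation (1260, 1660, 2040, 2345, 2500 m a.s.l.).
#' @seealso [total_fatty_acids()], [sat_unsat_ratio()]
#' @examples
#' fatty_acid_table()
#' @export
fatty_acid_table <- function() {
  data.frame(
    elevation_m      = c(1260, 1660, 2040, 2345, 2500),
    palmitic_mg_g    = c(24.232, 14.800, 23.611, 30.506, 47.185),
    linoleic_mg_g    = c(90.525, 67.969, 106.627, 174.380, 272.063),
    oleic_mg_g       = c(146.011, 97.199, 127.372, 84.317, 215.242),
    stearic_mg_g     = c(10.988, 8.227, 11.825, 14.193, 19.290),
    nonadecilic_mg_g = c(3.702, 3.709, 3.824, 4.760, 3.690)
  )
}
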