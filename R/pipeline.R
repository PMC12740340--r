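#' Full thermal-time analysis of germination time courses
#'
#' Runs the complete estimation chain on a long census table, per seed
#' lot (elevation): drop temperatures with zero germination everywhere;
#' fit the logistic to each (temperature, replicate) course
#' ([fit_sigmoid]); scale percentages to the lot maximum
#' ([scale_to_max]); invert each fit to times and rates for every
#' available percentile subpopulation; fit the asymmetric peak function
#' to rate versus temperature per (percentile, replicate) ([fit_peak]);
#' extract cardinal temperatures and thermal times from the tangents at
#' its inflection points ([tangent_cardinals]); and regress percentile
#' on thermal time per replicate ([percentile_tt_regression]).
#'
#' Non-converged or degenerate fits, and peak fits with fewer than five
#' usable temperatures or a boundary rate maximum, are excluded from
#' downstream steps and recorded in the `excluded` table.
#'
#' @param timecourses Long census data frame (columns as written by
#'   [write_timecourses()]).
#' @param percentiles Percentile subpopulations to analyse; default: the
#'   deciles available under the scaling rule of [scale_to_max()].
#' @param percentile_cap Passed to [scale_to_max()].
#' @param alpha Significance level used by downstream letter displays.
#' @return List of class `thermal_time_analysis` with data-frame
#'   elements `fits`, `rates`, `cardinals`, `tt_regressions`,
#'   `excluded`, and `scalings` (one [scale_to_max()] result per
#'   elevation).
#' @examples
#' \donttest{
#' cfg <- simulation_config(rng_seed = 11)
#' res <- analyze_thermal_time(simulate_population(cfg, elevation = 2345))
#' head(res$cardinals)
#' }
#' @export
analyze_thermal_time <- function(timecourses, percentiles = NULL,
                                 percentile_cap = 80, alpha = 0.05) {
  tc <- validate_timecourses(timecourses)
  fits <- list(); rates <- list(); cards <- list(); regs <- list()
  excluded <- list(); scalings <- list()
  note <- function(...) {
    excluded[[length(excluded) + 1L]] <<- data.frame(...)
  }
  for (elev in unique(tc$elevation)) {
    lot <- tc[tc$elevation == elev, ]
    # keep only temperatures where some germination occurred
    tot <- tapply(lot$cumulative_germinated, lot$temperature_C, max)
    keep_temps <- as.numeric(names(tot)[tot > 0])
    dropped <- setdiff(unique(lot$temperature_C), keep_temps)
    for (d in dropped)
      note(stage = "sigmoid", elevation = elev, temperature_C = d,
           percentile = NA_real_, replicate = NA_real_,
           reason = "zero germination at all replicates")
    lot <- lot[lot$temperature_C %in% keep_temps, ]
    if (nrow(lot) == 0L) next
    scaling <- scale_to_max(lot, percentile_cap = percentile_cap)
    scalings[[as.character(elev)]] <- scaling
    pcts <- if (is.null(percentiles)) scaling$percentiles else percentiles
    # 1. logistic fits per (temperature, replicate)
    lot_fits <- list()
    for (temp in sort(unique(lot$temperature_C))) {
      for (rep_i in sort(unique(lot$replicate[lot$temperature_C == temp]))) {
        d <- lot[lot$temperature_C == temp & lot$replicate == rep_i, ]
        d <- d[order(d$day), ]
        fit <- tryCatch(
          fit_sigmoid(d$day, d$cumulative_germinated, d$n_seeds[1L],
                      source = list(elevation = elev, temperature_C = temp,
                                    replicate = rep_i)),
          error = function(e) e)
        lag <- lag_time(d$day, d$cumulative_germinated)
        if (inherits(fit, "error")) {
          note(stage = "sigmoid", elevation = elev, temperature_C = temp,
               percentile = NA_real_, replicate = rep_i,
               reason = conditionMessage(fit))
          next
        }
        if (!fit$converged || fit$degenerate)
          note(stage = "sigmoid", elevation = elev, temperature_C = temp,
               percentile = NA_real_, replicate = rep_i,
               reason = if (fit$degenerate) "degenerate (saturated) fit"
                        else "non-convergent fit")
        fits[[length(fits) + 1L]] <- data.frame(
          elevation = elev, temperature_C = temp, replicate = rep_i,
          a = fit$a, b = fit$b, c = fit$c, r2 = fit$r2,
          lag_day = lag, converged = fit$converged,
          degenerate = fit$degenerate)
        if (fit$converged && !fit$degenerate)
          lot_fits[[length(lot_fits) + 1L]] <-
            list(temperature_C = temp, replicate = rep_i, fit = fit)
      }
    }
    # 2. times and rates per percentile
    for (lf in lot_fits) {
      for (g in pcts) {
        y_raw <- g / scaling$factor  # scaled percentile back to raw %
        t <- tryCatch(time_to_percentile(lf$fit, y_raw),
                      error = function(e) NA_real_)
        if (is.finite(t) && t > 0) {
          rates[[length(rates) + 1L]] <- data.frame(
            elevation = elev, percentile = g,
            temperature_C = lf$temperature_C, replicate = lf$replicate,
            time_day = t, rate = 1 / t)
        }
      }
    }
    lot_rates <- do.call(rbind, rates[vapply(rates, function(r)
      r$elevation[1L] == elev, logical(1))])
    if (is.null(lot_rates)) next
    # 3. peak fits and cardinals per (percentile, replicate)
    for (g in pcts) {
      for (rep_i in sort(unique(lot_rates$replicate))) {
        d <- lot_rates[lot_rates$percentile == g &
                         lot_rates$replicate == rep_i, ]
        if (length(unique(d$temperature_C)) < 5L) {
          note(stage = "peak", elevation = elev, temperature_C = NA_real_,
               percentile = g, replicate = rep_i,
               reason = "fewer than 5 usable temperatures")
          next
        }
        pk <- tryCatch(
          fit_peak(d$temperature_C, d$rate,
                   source = list(elevation = elev, percentile = g,
                                 replicate = rep_i)),
          error = function(e) e)
        if (inherits(pk, "error") || !pk$converged) {
          note(stage = "peak", elevation = elev, temperature_C = NA_real_,
               percentile = g, replicate = rep_i,
               reason = if (inherits(pk, "error")) conditionMessage(pk)
                        else "non-convergent peak fit")
          next
        }
        if (pk$descending_limb_missing) {
          note(stage = "peak", elevation = elev, temperature_C = NA_real_,
               percentile = g, replicate = rep_i,
               reason = "rate maximum at boundary temperature")
          next
        }
        card <- tryCatch(tangent_cardinals(pk), error = function(e) e)
        if (inherits(card, "error")) {
          note(stage = "cardinal", elevation = elev,
               temperature_C = NA_real_, percentile = g, replicate = rep_i,
               reason = conditionMessage(card))
          next
        }
        cards[[length(cards) + 1L]] <- data.frame(
          elevation = elev, percentile = g, replicate = rep_i,
          Tb_C = card$Tb, Tc_C = card$Tc,
          Ttsub_Cday = card$Ttsub, Ttsup_Cday = card$Ttsup,
          xmax_C = card$x_max, xmin_C = card$x_min, r2 = pk$r2)
      }
    }
    # 4. percentile ~ thermal time regressions per replicate
    lot_cards <- do.call(rbind, cards[vapply(cards, function(r)
      r$elevation[1L] == elev, logical(1))])
    if (!is.null(lot_cards)) {
      for (rep_i in sort(unique(lot_cards$replicate))) {
        d <- lot_cards[lot_cards$replicate == rep_i, ]
        for (rng in c("sub", "supra")) {
          tt <- if (rng == "sub") d$Ttsub_Cday else d$Ttsup_Cday
          reg <- tryCatch(percentile_tt_regression(d$percentile, tt, rng),
                          error = function(e) NULL)
          if (!is.null(reg))
            regs[[length(regs) + 1L]] <- data.frame(
              elevation = elev, replicate = rep_i, range = rng,
              slope = reg$slope, intercept = reg$intercept,
              r2 = reg$r2, n = reg$n)
        }
      }
    }
  }
  bindrows <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(fits = bindrows(fits), rates = bindrows(rates),
                 cardinals = bindrows(cards),
                 tt_regressions = bindrows(regs),
                 excluded = bindrows(excluded), scalings = scalings,
                 alpha = alpha),
            class = "thermal_time_analysis")
}

#' @export
print.thermal_time_analysis <- function(x, ...) {
  cat("Thermal-time analysis\n")
  cat(sprintf("  %d logistic fits, %d cardinal estimates, %d exclusions\n",
              if (is.null(x$fits)) 0L else nrow(x$fits),
              if (is.null(x$cardinals)) 0L else nrow(x$cardinals),
              if (is.null(x$excluded)) 0L else nrow(x$excluded)))
  if (!is.null(x$cardinals)) {
    cat(sprintf("  grand means: Tb %.2f degC, Tc %.2f degC\n",
                mean(x$cardinals$Tb_C), mean(x$cardinals$Tc_C)))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects inputs, numerical settings and output location for
#' [run_pipeline()]. When `timecourse_path` is `NULL` the germination
#' data are simulated with [simulate_population()], one seed lot per
#' entry of `elevations` with the matching `viabilities`; when
#' `soil_trace_path` is `NULL` a diurnal trace is simulated with
#' [simulate_soil_trace()]; when `fatty_acid_path` is `NULL` the
#' built-in [fatty_acid_table()] is used.
#'
#' @param output_dir Directory for result tables (created if needed).
#' @param timecourse_path,soil_trace_path,fatty_acid_path Optional input
#'   CSVs; must exist when given.
#' @param elevations Elevations (m) of the simulated seed lots.
#' @param viabilities Viability of each simulated lot (recycled).
#' @param base_config A [simulation_config()] supplying all other
#'   generator settings.
#' @param percentiles,percentile_cap,alpha Passed to
#'   [analyze_thermal_time()].
#' @param window,dd_convention Degree-day window (hours) and
#'   accumulation convention (see [accumulate_degree_days()]).
#' @param t_o Optimal temperature for degree-day clipping (degC).
#' @param tt_target Target thermal time (degC day) for the days-to-reach
#'   prediction; default: the lot-mean 50th-percentile suboptimal
#'   thermal time estimated by the pipeline itself.
#' @param trace_mean,trace_amplitude,trace_noise_sd,trace_days,trace_interval
#'   Settings of the simulated soil trace.
#' @param rng_seed Integer master seed for all simulated inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            timecourse_path = NULL,
                            soil_trace_path = NULL,
                            fatty_acid_path = NULL,
                            elevations = c(1260, 1660, 2040, 2345, 2500),
                            viabilities = c(0.78, 0.92, 0.67, 0.55, 0.58),
                            base_config = simulation_config(),
                            percentiles = NULL,
                            percentile_cap = 80,
                            alpha = 0.05,
                            window = c(8, 18),
                            dd_convention = "excess",
                            t_o = NULL,
                            tt_target = NULL,
                            trace_mean = 22, trace_amplitude = 8,
                            trace_noise_sd = 0.5, trace_days = 7,
                            trace_interval = 30,
                            rng_seed = 1L) {
  for (p in c(timecourse_path, soil_trace_path, fatty_acid_path))
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
  if (!is.null(percentiles) && !all(percentiles %in% seq(10, 80, 10)))
    stop("percentiles must be a subset of {10, 20, ..., 80}")
  validate_simulation_config(base_config)
  structure(list(output_dir = output_dir,
                 timecourse_path = timecourse_path,
                 soil_trace_path = soil_trace_path,
                 fatty_acid_path = fatty_acid_path,
                 elevations = elevations,
                 viabilities = rep_len(viabilities, length(elevations)),
                 base_config = base_config,
                 percentiles = percentiles,
                 percentile_cap = percentile_cap, alpha = alpha,
                 window = window, dd_convention = dd_convention,
                 t_o = t_o, tt_target = tt_target,
                 trace_mean = trace_mean,
                 trace_amplitude = trace_amplitude,
                 trace_noise_sd = trace_noise_sd,
                 trace_days = trace_days,
                 trace_interval = trace_interval,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the whole germination analysis pipeline
#'
#' Executes, in order: data acquisition (read or simulate), logistic
#' fits, percentile rates, peak fits and cardinal estimates, percentile
#' versus thermal-time regressions, aggregation with Tukey letters,
#' degree-day accumulation and days-to-target prediction, and
#' fatty-acid summaries; writes every result table as CSV into
#' `config$output_dir` together with a run log (seed, package version,
#' exclusion counts). A failure in any stage aborts with a stage-tagged
#' error and removes the files written so far; a seeded run is
#' deterministic.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the analysis object, the aggregated
#'   cardinal table, the degree-day summary, the biochemistry table and
#'   the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$output_dir, name)
    write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8",
              quote = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_lines <- c(sprintf("thermogerm %s pipeline run",
                         as.character(utils::packageVersion("thermogerm"))),
                 sprintf("rng_seed: %d", config$rng_seed),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  # -- inputs -----------------------------------------------------------
  tc <- stage("input", {
    if (!is.null(config$timecourse_path)) {
      read_timecourses(config$timecourse_path)
    } else {
      lots <- vector("list", length(config$elevations))
      for (i in seq_along(config$elevations)) {
        cfg_i <- config$base_config
        cfg_i$viability <- config$viabilities[i]
        cfg_i$rng_seed <- config$rng_seed + i
        lots[[i]] <- simulate_population(cfg_i,
                                         elevation = config$elevations[i])
      }
      do.call(rbind, lots)
    }
  })
  trace <- stage("input", {
    if (!is.null(config$soil_trace_path)) read_soil_trace(config$soil_trace_path)
    else simulate_soil_trace(config$trace_mean, config$trace_amplitude,
                             config$trace_noise_sd, config$trace_days,
                             config$trace_interval,
                             rng_seed = config$rng_seed + 1000L)
  })
  fa <- stage("input", {
    if (!is.null(config$fatty_acid_path)) read.csv(config$fatty_acid_path)
    else fatty_acid_table()
  })
  if (is.null(config$timecourse_path)) emit(tc, "timecourses.csv")
  if (is.null(config$soil_trace_path)) emit(trace, "soil_trace.csv")
  # -- thermal-time analysis -------------------------------------------
  res <- stage("thermal_time", analyze_thermal_time(
    tc, percentiles = config$percentiles,
    percentile_cap = config$percentile_cap, alpha = config$alpha))
  stage("thermal_time", {
    if (is.null(res$cardinals)) stop("no cardinal estimates produced")
  })
  emit(res$fits, "sigmoid_fits.csv")
  emit(res$rates, "percentile_rates.csv")
  emit(res$cardinals, "cardinals.csv")
  if (!is.null(res$tt_regressions)) emit(res$tt_regressions,
                                         "tt_regressions.csv")
  summary_tab <- stage("aggregate",
                       aggregate_cardinals(res$cardinals,
                                           alpha = config$alpha))
  emit(summary_tab, "cardinals_summary.csv")
  # -- degree-days ------------------------------------------------------
  dd <- stage("degree_days", {
    t_b <- mean(res$cardinals$Tb_C)
    t_o <- if (is.null(config$t_o)) mean(res$cardinals$xmin_C) else config$t_o
    accumulate_degree_days(trace, t_b = t_b, t_o = t_o,
                           window = config$window,
                           convention = config$dd_convention)
  })
  tt_target <- stage("degree_days", {
    if (!is.null(config$tt_target)) config$tt_target
    else {
      p50 <- res$cardinals[res$cardinals$percentile == 50, ]
      if (nrow(p50) == 0L) stop("no 50th-percentile thermal time available")
      mean(p50$Ttsub_Cday)
    }
  })
  days <- days_to_thermal_time(tt_target, dd$mean)
  emit(data.frame(t_b = dd$t_b, t_o = dd$t_o,
                  window_start_h = dd$window[1L], window_end_h = dd$window[2L],
                  convention = dd$convention,
                  daily_units_Cday = dd$mean, daily_units_sd = dd$sd,
                  n_days = dd$n_days, tt_target_Cday = tt_target,
                  days_to_target = days), "degree_days.csv")
  # -- biochemistry -----------------------------------------------------
  bio <- stage("biochem", {
    tot <- t(vapply(seq_len(nrow(fa)), function(i) total_fatty_acids(fa[i, ]),
                    numeric(2)))
    data.frame(fa, total_mg_g = tot[, "total_mg_g"],
               total_pct = tot[, "total_pct"],
               sat_unsat_ratio = vapply(seq_len(nrow(fa)), function(i)
                 sat_unsat_ratio(fa[i, ]), numeric(1)))
  })
  emit(bio, "fatty_acid_summary.csv")
  # -- log --------------------------------------------------------------
  n_excl <- if (is.null(res$excluded)) 0L else nrow(res$excluded)
  log_lines <- c(log_lines, sprintf("excluded fits: %d", n_excl))
  if (n_excl > 0) {
    ex <- res$excluded
    log_lines <- c(log_lines, sprintf(
      "  [%s] elevation %s, temperature %s, percentile %s, replicate %s: %s",
      ex$stage, ex$elevation, ex$temperature_C, ex$percentile, ex$replicate,
      ex$reason))
  }
  log_path <- file.path(config$output_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)
  invisible(list(analysis = res, summary = summary_tab, degree_days = dd,
                 days_to_target = days, biochem = bio, files = written))
}
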