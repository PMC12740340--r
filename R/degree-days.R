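#' Summary statistics of a soil-temperature trace
#'
#' @param trace A `soil_trace` data frame (columns `timestamp_minutes`,
#'   `temperature_C`), e.g. from [simulate_soil_trace()] or
#'   [read_soil_trace()].
#' @return Named numeric vector `min`, `mean`, `max` (degC).
#' @export
summarize_trace <- function(trace) {
  trace <- validate_soil_trace(trace)
  x <- trace$temperature_C
  if (length(x) == 0L) stop("empty soil trace")
  c(min = min(x), mean = mean(x), max = max(x))
}

validate_soil_trace <- function(trace) {
  if (!all(c("timestamp_minutes", "temperature_C") %in% names(trace)))
    stop("soil trace needs columns timestamp_minutes and temperature_C")
  if (nrow(trace) == 0L) stop("empty soil trace")
  if (any(!is.finite(trace$temperature_C)))
    stop("soil trace temperatures must be finite")
  dt <- diff(trace$timestamp_minutes)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (length(dt) && max(abs(dt - dt[1L])) > 1e-8)
    stop("timestamps must be equally spaced")
  if (is.null(attr(trace, "interval")))
    attr(trace, "interval") <- if (length(dt)) dt[1L] else NA_real_
  trace
}

#' Degree-day accumulation over a diurnal window
#'
#' For each whole day of the trace, sums the excess of soil temperature
#' above the base temperature `t_b`, clipped at the optimal temperature
#' `t_o`, over readings whose time of day falls in `window`, weighting
#' each reading by its full sampling interval (left-closed rule). The
#' degC h total is divided by 24 to express it in degC day per calendar
#' day. Days with missing in-window readings are dropped.
#'
#' The clipped-excess integrand \eqn{(\min(T, T_o) - T_b)^+} is the
#' standard degree-day definition and makes the accumulated units
#' commensurable with thermal times estimated as reciprocal tangent
#' slopes; `convention = "raw"` instead sums the raw temperature of
#' readings lying inside \[`t_b`, `t_o`\].
#'
#' @param trace A `soil_trace` covering at least one full day.
#' @param t_b Base temperature (degC).
#' @param t_o Optimal temperature (degC), `> t_b`.
#' @param window Numeric length-2, start and end hour of the diurnal
#'   window within one day (default `c(8, 18)`); readings with
#'   `start <= hour < end` are used.
#' @param convention `"excess"` (default) or `"raw"` (see Details).
#' @return List of class `degree_day_summary`: `daily` (degC day
#'   accumulated in each complete day), `mean`, `sd`, `n_days`,
#'   `window`, `t_b`, `t_o`, `convention`.
#' @examples
#' tr <- simulate_soil_trace(22.5, 0, 0, days = 5, interval = 30)
#' accumulate_degree_days(tr, t_b = 10.5, t_o = 29, window = c(0, 24))$mean
#' @export
accumulate_degree_days <- function(trace, t_b, t_o, window = c(8, 18),
                                   convention = c("excess", "raw")) {
  convention <- match.arg(convention)
  trace <- validate_soil_trace(trace)
  stopifnot(is.finite(t_b), is.finite(t_o))
  if (t_b >= t_o) stop("t_b must be below t_o")
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] < 0 || window[2L] > 24)
    stop("window must be (start, end) hours with 0 <= start < end <= 24")
  interval <- attr(trace, "interval")
  tmin <- trace$timestamp_minutes
  if (max(tmin) - min(tmin) + interval < 1440)
    stop("trace must cover at least one full day")
  day_idx <- floor(tmin / 1440)
  hour <- (tmin %% 1440) / 60
  in_win <- hour >= window[1L] & hour < window[2L]
  expected <- round((window[2L] - window[1L]) * 60 / interval)
  dt_h <- interval / 60
  temp <- trace$temperature_C
  contrib <- switch(convention,
    excess = pmax(pmin(temp, t_o) - t_b, 0),
    raw = ifelse(temp >= t_b & temp <= t_o, temp, 0))
  daily <- c()
  for (d in sort(unique(day_idx))) {
    sel <- in_win & day_idx == d
    if (sum(sel) != expected) next  # incomplete day: drop, never impute
    daily <- c(daily, sum(contrib[sel]) * dt_h / 24)
  }
  if (length(daily) == 0L)
    stop("no complete day with full in-window coverage")
  structure(list(daily = daily, mean = mean(daily),
                 sd = if (length(daily) > 1L) sd(daily) else NA_real_,
                 n_days = length(daily), window = window,
                 t_b = t_b, t_o = t_o, convention = convention),
            class = "degree_day_summary")
}

#' @export
print.degree_day_summary <- function(x, ...) {
  cat(sprintf(
    "Degree-days (%s, window %g-%g h, Tb %.2f, To %.2f): %.2f +/- %s degC day/day over %d day(s)\n",
    x$convention, x$window[1L], x$window[2L], x$t_b, x$t_o, x$mean,
    ifelse(is.na(x$sd), "NA", sprintf("%.2f", x$sd)), x$n_days))
  invisible(x)
}

#' Days needed to accumulate a target thermal time
#'
#' @param tt_target Target thermal time (degC day), non-negative.
#' @param daily_units Degree-days accumulated per day (degC day/day),
#'   positive; typically the `mean` of [accumulate_degree_days()].
#' @return Continuous number of days `tt_target / daily_units` (callers
#'   may round up to whole days).
#' @examples
#' days_to_thermal_time(62.5, 25.6)
#' @export
days_to_thermal_time <- function(tt_target, daily_units) {
  stopifnot(is.numeric(tt_target), is.numeric(daily_units))
  if (any(!is.finite(daily_units) | daily_units <= 0))
    stop("daily_units must be positive")
  if (any(!is.finite(tt_target) | tt_target < 0))
    stop("tt_target must be non-negative")
  tt_target / daily_units
}

#' Elevational lapse model for temperature
#'
#' Fits the cubic-in-elevation lapse model \eqn{Y = a + b x^3} (with `Y`
#' temperature and `x` elevation) by least squares, and also reports the
#' endpoint rate of change: the temperature drop between the lowest and
#' highest sites per 100 m of elevation.
#'
#' @param elevation Elevations (m a.s.l.), at least 3 distinct.
#' @param temperature Temperatures (degC) at those elevations.
#' @return List of class `lapse_fit`: `a` (degC), `b` (degC m^-3), `r2`,
#'   `rate_per_100m` (degC per 100 m, positive when temperature falls
#'   with elevation), `n`.
#' @examples
#' fit_lapse(c(1260, 1660, 2040, 2345, 2500),
#'           c(25, 22.1, 19.3, 16.8, 15.3))$rate_per_100m
#' @export
fit_lapse <- function(elevation, temperature) {
  stopifnot(is.numeric(elevation), is.numeric(temperature),
            length(elevation) == length(temperature))
  keep <- is.finite(elevation) & is.finite(temperature)
  elevation <- elevation[keep]; temperature <- temperature[keep]
  if (length(unique(elevation)) < 3L)
    stop("need at least 3 distinct elevations")
  x3 <- elevation^3
  fit <- lm(temperature ~ x3)
  s <- summary(fit)
  i_lo <- which.min(elevation); i_hi <- which.max(elevation)
  rate <- (temperature[i_lo] - temperature[i_hi]) /
    ((elevation[i_hi] - elevation[i_lo]) / 100)
  structure(list(a = unname(coef(fit)[1L]), b = unname(coef(fit)[2L]),
                 r2 = s$r.squared, rate_per_100m = rate,
                 n = length(elevation)),
            class = "lapse_fit")
}

#' @export
print.lapse_fit <- function(x, ...) {
  cat(sprintf("Lapse model Y = a + b x^3: a = %.4g degC, b = %.4g degC/m^3, r2 = %.4f\n",
              x$a, x$b, x$r2))
  cat(sprintf("  endpoint rate: %.3f degC per 100 m\n", x$rate_per_100m))
  invisible(x)
}
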