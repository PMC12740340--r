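#' The asymmetric peak function for germination rate versus temperature
#'
#' Evaluates \eqn{GR(T) = a \exp(-b (T/c - 1)^2 + 1/(T - d))}, a
#' unimodal, right-truncated curve: `a` sets the maximal rate, `b` the
#' width (a \eqn{1/\sigma^2}-like parameter), `c` the temperature of the
#' maximal rate, and `d` the abscissa intercept of the descending limb
#' (the rate tends to zero as `T` approaches `d` from below; the
#' function is undefined at and beyond `d`).
#'
#' @param temp Temperature(s) in degC, all strictly below `d`.
#' @param a,b,c,d Parameters (`a > 0`, `b > 0`, `c < d`, `c != 0`).
#' @return Germination rate(s) in 1/day.
#' @examples
#' peak_function(29, a = 0.3, b = 5, c = 29, d = 35)  # 0.3 * exp(-1/6)
#' @export
peak_function <- function(temp, a, b, c, d) {
  if (any(!is.finite(temp))) stop("temperature must be finite")
  if (any(temp >= d))
    stop("peak function undefined at or beyond the descending intercept d")
  a * exp(-b * (temp / c - 1)^2 + 1 / (temp - d))
}

#' Evaluate a fitted peak curve
#'
#' @param fit A [fit_peak()] object or list with `a`, `b`, `c`, `d`.
#' @param temp Temperature(s), strictly below `fit$d`.
#' @return Rate(s) in 1/day.
#' @export
peak_value <- function(fit, temp) {
  peak_function(temp, fit$a, fit$b, fit$c, fit$d)
}

#' Construct a peak-curve object from known parameters
#'
#' Mainly for evaluating [tangent_cardinals()] on analytically specified
#' curves; [fit_peak()] produces the same structure from data.
#'
#' @param a,b,c,d Peak-function parameters (see [peak_function()]).
#' @param t_min Lowest temperature of the data the curve describes
#'   (bounds the ascending-limb inflection search); defaults to a wide
#'   bound below the peak when unknown.
#' @return Object of class `peak_fit`.
#' @export
peak_fit <- function(a, b, c, d, t_min = NULL) {
  stopifnot(a > 0, b > 0, is.finite(c), is.finite(d), c < d, c != 0)
  new_peak_fit(a, b, c, d, r2 = NA_real_, converged = TRUE,
               descending_limb_missing = FALSE, t_min = t_min,
               n = NA_integer_)
}

new_peak_fit <- function(a, b, c, d, r2, converged, descending_limb_missing,
                         t_min, n) {
  structure(list(a = a, b = b, c = c, d = d, r2 = r2, converged = converged,
                 descending_limb_missing = descending_limb_missing,
                 t_min = t_min, n = n),
            class = "peak_fit")
}

#' @export
coef.peak_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c, d = object$d)
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("Asymmetric peak fit: GR(T) = a exp(-b (T/c - 1)^2 + 1/(T - d))\n")
  cat(sprintf("  a = %.4g 1/day, b = %.4g, c = %.4g degC, d = %.4g degC",
              x$a, x$b, x$c, x$d))
  if (is.finite(x$r2)) cat(sprintf(", r2 = %.4f", x$r2))
  cat("\n")
  if (x$descending_limb_missing)
    cat("  [warning: empirical maximum at a boundary temperature]\n")
  if (!x$converged) cat("  [did not converge]\n")
  invisible(x)
}

#' Fit the asymmetric peak function to rate-temperature pairs
#'
#' Levenberg-Marquardt least squares of [peak_function()] on germination
#' rate versus incubation temperature for one percentile cohort.
#' Initialisation: `c0` at the empirical rate maximum, `d0` two degrees
#' above the warmest observation, `a0` the maximal rate back-corrected
#' for the tail term, `b0 = 4`; a small multistart grid on `(b0, d0)` is
#' tried and the lowest-deviance converged fit kept.
#'
#' @param temp Temperatures (degC), at least 5 distinct values.
#' @param rate Germination rates (1/day) at `temp`.
#' @param ftol Convergence tolerance on the residual sum of squares.
#' @param source Optional identifier stored with the fit.
#' @return Object of class `peak_fit` (see [peak_fit()]); the element
#'   `descending_limb_missing` flags an empirical maximum at a boundary
#'   temperature, and `converged = FALSE` marks a failed fit (excluded
#'   from downstream averaging).
#' @examples
#' T <- c(11, 14, 17, 21, 23, 25, 28, 31, 33)
#' gr <- peak_function(T, 0.3, 5, 29, 35)
#' coef(fit_peak(T, gr))
#' @export
fit_peak <- function(temp, rate, ftol = 1e-10, source = NULL) {
  stopifnot(is.numeric(temp), is.numeric(rate), length(temp) == length(rate))
  keep <- is.finite(temp) & is.finite(rate)
  temp <- temp[keep]; rate <- rate[keep]
  if (length(unique(temp)) < 5L)
    stop("need at least 5 distinct temperatures to fit 4 parameters")
  if (stats::var(rate) == 0) stop("all rates equal; peak curve undetermined")
  ord <- order(temp)
  temp <- temp[ord]; rate <- rate[ord]
  imax <- which.max(rate)
  descending_limb_missing <- imax == 1L || imax == length(rate)
  c0 <- temp[imax]
  tmax <- max(temp)
  d_lo <- tmax + 1e-4
  starts <- list(c(b = 4, d = tmax + 2), c(b = 1, d = tmax + 1),
                 c(b = 12, d = tmax + 5), c(b = 4, d = tmax + 8))
  best <- NULL
  for (st in starts) {
    a0 <- max(rate) / exp(1 / (c0 - st[["d"]]))
    fit <- tryCatch(
      minpack.lm::nlsLM(rate ~ a * exp(-b * (temp / c - 1)^2 + 1 / (temp - d)),
                        start = list(a = a0, b = st[["b"]], c = c0,
                                     d = st[["d"]]),
                        lower = c(a = 1e-9, b = 1e-9, c = min(temp) / 2,
                                  d = d_lo),
                        control = minpack.lm::nls.lm.control(
                          ftol = ftol, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      # validity of the peak form: the rate maximum must sit below the
      # descending abscissa intercept
      if (cf[["c"]] >= cf[["d"]]) next
      dev <- sum(resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) {
    out <- new_peak_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                        r2 = NA_real_, converged = FALSE,
                        descending_limb_missing = descending_limb_missing,
                        t_min = min(temp), n = length(temp))
    out$source <- source
    return(out)
  }
  cf <- coef(best$fit)
  r2 <- 1 - best$dev / sum((rate - mean(rate))^2)
  out <- new_peak_fit(unname(cf["a"]), unname(cf["b"]), unname(cf["c"]),
                      unname(cf["d"]), r2 = r2, converged = TRUE,
                      descending_limb_missing = descending_limb_missing,
                      t_min = min(temp), n = length(temp))
  out$source <- source
  out
}

# central-difference first derivative of a fitted peak curve
peak_derivative <- function(fit, temp, h = 1e-5) {
  (peak_value(fit, temp + h) - peak_value(fit, temp - h)) / (2 * h)
}

default_lower_bound <- function(fit) {
  if (!is.null(fit$t_min) && is.finite(fit$t_min)) return(fit$t_min - 5)
  # no data range recorded: bound well below the ascending inflection of
  # the Gaussian core, c (1 - 1/sqrt(2 b))
  fit$c * (1 - 2 / sqrt(2 * fit$b)) - 1
}

#' Inflection temperatures of a fitted peak curve
#'
#' Locates the temperatures of the first maximum (`x_max`, ascending
#' limb) and first minimum (`x_min`, descending limb) of the curve's
#' first derivative. The derivative is computed by central differences
#' (step `1e-5` degC), bracketed on a dense grid (step `1e-3` degC) and
#' refined by golden-section/Brent search within the bracketing cell.
#'
#' @param fit A `peak_fit`.
#' @param lower Lower bound of the ascending-limb search; defaults to
#'   the coldest observed temperature minus 5 degC.
#' @param grid_step Grid spacing (degC) for bracketing.
#' @return List with `x_max`, `x_min` (degC) and `boundary` (`TRUE` if
#'   either extremum sat on a search boundary).
#' @examples
#' inflection_points(peak_fit(0.3, 5, 29, 35, t_min = 11))
#' @export
inflection_points <- function(fit, lower = NULL, grid_step = 1e-3) {
  if (!isTRUE(fit$converged)) stop("cannot locate inflections of a failed fit")
  if (is.null(lower)) lower <- default_lower_bound(fit)
  if (lower >= fit$c) stop("lower search bound must lie below c")
  dfun <- function(x) peak_derivative(fit, x)
  bracket_extremum <- function(from, to, maximum) {
    xs <- seq(from, to, by = grid_step)
    fp <- dfun(xs)
    i <- if (maximum) which.max(fp) else which.min(fp)
    at_boundary <- i == 1L || i == length(xs)
    lo <- xs[max(1L, i - 1L)]
    hi <- xs[min(length(xs), i + 1L)]
    opt <- optimize(dfun, interval = c(lo, hi), maximum = maximum,
                    tol = 1e-9)
    x <- if (maximum) opt$maximum else opt$minimum
    list(x = x, boundary = at_boundary)
  }
  up <- bracket_extremum(lower, fit$c - grid_step, maximum = TRUE)
  dn <- bracket_extremum(fit$c + grid_step, fit$d - grid_step,
                         maximum = FALSE)
  list(x_max = up$x, x_min = dn$x, boundary = up$boundary || dn$boundary)
}

#' Base and ceiling temperatures and thermal times from tangent lines
#'
#' Draws the tangent to the fitted peak curve at each inflection point
#' and extrapolates it to the abscissa. With `y` the rate and `s` the
#' slope at an inflection temperature `x`, the tangent's intercept is
#' `ORD = y - s x`; the base temperature is \eqn{T_b = -ORD_{max} /
#' s_{max}} (ascending limb), the ceiling \eqn{T_c = -ORD_{min} /
#' s_{min}} (descending limb), and the thermal times are the reciprocal
#' tangent slopes, \eqn{\theta_{sub} = 1/s_{max}} and
#' \eqn{\theta_{sup} = 1/|s_{min}|} (degC day).
#'
#' @inheritParams inflection_points
#' @return Object of class `cardinal_estimates`: list with `Tb`, `Tc`
#'   (degC), `Ttsub`, `Ttsup` (degC day) and the intermediates `x_max`,
#'   `x_min`, `y_max`, `y_min`, `slope_max`, `slope_min`, `ORD_max`,
#'   `ORD_min`, plus the `boundary` flag of the inflection search.
#' @examples
#' card <- tangent_cardinals(peak_fit(0.3, 5, 29, 35, t_min = 11))
#' c(card$Tb, card$Tc)
#' @export
tangent_cardinals <- function(fit, lower = NULL, grid_step = 1e-3) {
  infl <- inflection_points(fit, lower = lower, grid_step = grid_step)
  x_max <- infl$x_max; x_min <- infl$x_min
  y_max <- peak_value(fit, x_max)
  y_min <- peak_value(fit, x_min)
  slope_max <- peak_derivative(fit, x_max)
  slope_min <- peak_derivative(fit, x_min)
  if (abs(slope_max) < 1e-12 || abs(slope_min) < 1e-12)
    stop("degenerate tangent: zero slope at an inflection point")
  ORD_max <- y_max - slope_max * x_max
  ORD_min <- y_min - slope_min * x_min
  structure(list(Tb = -ORD_max / slope_max,
                 Tc = -ORD_min / slope_min,
                 Ttsub = 1 / slope_max,
                 Ttsup = 1 / abs(slope_min),
                 x_max = x_max, x_min = x_min,
                 y_max = y_max, y_min = y_min,
                 slope_max = slope_max, slope_min = slope_min,
                 ORD_max = ORD_max, ORD_min = ORD_min,
                 boundary = infl$boundary),
            class = "cardinal_estimates")
}

#' @export
print.cardinal_estimates <- function(x, ...) {
  cat("Cardinal estimates from inflection-point tangents\n")
  cat(sprintf("  Tb = %.3f degC (x_max %.3f, slope %.4g 1/day/degC)\n",
              x$Tb, x$x_max, x$slope_max))
  cat(sprintf("  Tc = %.3f degC (x_min %.3f, slope %.4g 1/day/degC)\n",
              x$Tc, x$x_min, x$slope_min))
  cat(sprintf("  Ttsub = %.2f degC day, Ttsup = %.2f degC day\n",
              x$Ttsub, x$Ttsup))
  invisible(x)
}

#' Linear regression of percentile subpopulation on thermal time
#'
#' @param percentile Percentile subpopulations (percent of scaled
#'   maximum), at least 3.
#' @param tt Thermal times (degC day) for those percentiles.
#' @param range `"sub"` or `"supra"` (label only).
#' @return List of class `tt_regression`: `slope` (percent per degC
#'   day), `intercept` (percent), `r2`, `range`, `n`.
#' @examples
#' r <- percentile_tt_regression(c(10, 30, 50), c(10, 20, 30), "sub")
#' r$slope
#' @export
percentile_tt_regression <- function(percentile, tt,
                                     range = c("sub", "supra")) {
  range <- match.arg(range)
  keep <- is.finite(percentile) & is.finite(tt)
  percentile <- percentile[keep]; tt <- tt[keep]
  if (length(percentile) < 3L) stop("need at least 3 percentiles")
  if (stats::var(tt) == 0) stop("thermal times are constant; slope undefined")
  fit <- lm(percentile ~ tt)
  s <- summary(fit)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = s$r.squared, range = range, n = length(percentile)),
            class = "tt_regression")
}

#' @export
print.tt_regression <- function(x, ...) {
  cat(sprintf("%soptimal percentile ~ thermal time: slope %.3f %%/degC day, intercept %.2f, r2 %.4f (n = %d)\n",
              x$range, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Aggregate per-replicate cardinal estimates
#'
#' Summarises a per-replicate cardinal table (as produced by
#' [analyze_thermal_time()]) into mean, SD and n per (elevation,
#' percentile) cell, with Tukey compact letters comparing percentiles
#' within each elevation for every measure; an attribute carries the
#' complementary letters comparing elevations within each percentile.
#'
#' @param cardinals Data frame with columns `elevation`, `percentile`,
#'   `replicate`, `Tb_C`, `Tc_C`, `Ttsub_Cday`, `Ttsup_Cday`.
#' @param alpha Significance level for the letter displays.
#' @return Data frame with one row per (elevation, percentile): `n`,
#'   and for each measure its `_mean`, `_sd` and `_letter` (within
#'   elevation, across percentiles). Attribute
#'   `between_elevation_letters` holds a long data frame of letters
#'   comparing elevations within each percentile. Cells with fewer than
#'   2 replicates are dropped with a warning.
#' @export
aggregate_cardinals <- function(cardinals, alpha = 0.05) {
  need <- c("elevation", "percentile", "replicate",
            "Tb_C", "Tc_C", "Ttsub_Cday", "Ttsup_Cday")
  if (!all(need %in% names(cardinals)))
    stop("cardinals must contain columns: ", paste(need, collapse = ", "))
  measures <- c("Tb_C", "Tc_C", "Ttsub_Cday", "Ttsup_Cday")
  cardinals <- cardinals[stats::complete.cases(cardinals[measures]), ]
  cell <- interaction(cardinals$elevation, cardinals$percentile, drop = TRUE)
  sizes <- table(cell)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("dropping cells with < 2 replicates: ",
            paste(small, collapse = ", "))
    cardinals <- cardinals[!(cell %in% small), ]
  }
  agg <- function(v, f) {
    out <- aggregate(cardinals[[v]],
                     by = list(elevation = cardinals$elevation,
                               percentile = cardinals$percentile), FUN = f)
    out$x
  }
  base <- aggregate(cardinals$Tb_C,
                    by = list(elevation = cardinals$elevation,
                              percentile = cardinals$percentile),
                    FUN = length)
  res <- data.frame(elevation = base$elevation, percentile = base$percentile,
                    n = base$x)
  letter_lookup <- function(v, by_col, within_col) {
    # letters for `v` comparing levels of by_col within each within_col
    out <- list()
    for (w in unique(cardinals[[within_col]])) {
      d <- cardinals[cardinals[[within_col]] == w, ]
      lt <- tryCatch({
        if (length(unique(d[[by_col]])) < 2L) stop("single group")
        compare_groups(d[[v]], d[[by_col]], alpha = alpha)$letters
      }, error = function(e) NULL)
      if (!is.null(lt))
        out[[length(out) + 1L]] <- data.frame(
          within = w, level = names(lt), letter = unname(lt))
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  between <- list()
  for (v in measures) {
    res[[paste0(v, "_mean")]] <- agg(v, mean)
    res[[paste0(v, "_sd")]] <- agg(v, sd)
    wl <- letter_lookup(v, "percentile", "elevation")
    res[[paste0(v, "_letter")]] <- if (is.null(wl)) NA_character_ else {
      key <- paste(res$elevation, res$percentile)
      wl_key <- paste(wl$within, wl$level)
      wl$letter[match(key, wl_key)]
    }
    bl <- letter_lookup(v, "elevation", "percentile")
    if (!is.null(bl)) {
      bl$measure <- v
      names(bl)[1:2] <- c("percentile", "elevation")
      between[[v]] <- bl
    }
  }
  res <- res[order(res$elevation, res$percentile), ]
  rownames(res) <- NULL
  attr(res, "between_elevation_letters") <-
    if (length(between)) do.call(rbind, c(between, make.row.names = FALSE)) else NULL
  res
}
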