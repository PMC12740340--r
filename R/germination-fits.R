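#' Fit a logistic curve to one cumulative germination time course
#'
#' Least-squares fit of the three-parameter logistic
#' \eqn{y(t) = a / (1 + b e^{-c t})} to cumulative germination
#' percentages, where `a` is the asymptotic germination percentage, `b`
#' a shape parameter and `c` the rate constant (1/day). Fitting uses
#' Levenberg-Marquardt with self-starting values (`a0` the maximum
#' observed percentage, `c0` from the log-slope between the 25% and 75%
#' crossings of `a0`, `b0` from the first nonzero observation) plus two
#' jittered restarts before declaring non-convergence.
#'
#' @param day Census days (positive, strictly increasing).
#' @param count Cumulative germinated counts at `day`.
#' @param n_seeds Seeds sown.
#' @param ftol Convergence tolerance on the residual sum of squares.
#' @param source Optional identifier (e.g. list of elevation,
#'   temperature, replicate) stored with the fit.
#'
#' @return Object of class `sigmoid_fit`: list with elements `a`, `b`,
#'   `c`, `r2`, `converged`, `degenerate`, `n`, `source`. A saturated
#'   course (constant nonzero count from the first census) is returned
#'   with `a` equal to that percentage and `degenerate = TRUE` rather
#'   than fitted.
#' @examples
#' t <- 1:30
#' y <- 90 / (1 + 15 * exp(-0.6 * t))          # exact logistic, a = 90%
#' fit <- fit_sigmoid(t, round(y / 2), 50)      # counts out of 50 seeds
#' coef(fit)
#' @export
fit_sigmoid <- function(day, count, n_seeds, ftol = 1e-10, source = NULL) {
  stopifnot(is.numeric(day), is.numeric(count), length(day) == length(count),
            n_seeds >= 1)
  if (any(diff(day) <= 0)) stop("day must be strictly increasing")
  if (any(count < 0 | count > n_seeds))
    stop("counts must lie in [0, n_seeds]")
  if (any(diff(count) < 0)) stop("cumulative counts must be nondecreasing")
  if (nrow(unique(cbind(day, count))) < 4L)
    stop("need at least 4 distinct (day, count) points")
  if (all(count == 0))
    stop(no_germination_error("all counts are zero; nothing to fit"))
  pct <- 100 * count / n_seeds
  if (stats::var(pct) == 0) {
    # saturated from the first census: asymptote observed, rate unresolvable
    return(new_sigmoid_fit(a = pct[1L], b = NA_real_, c = NA_real_, r2 = 1,
                           converged = FALSE, degenerate = TRUE,
                           n = length(day), source = source))
  }
  a0 <- max(pct)
  i25 <- which(pct >= 0.25 * a0)[1L]
  i75 <- which(pct >= 0.75 * a0)[1L]
  c0 <- if (!is.na(i75) && day[i75] > day[i25]) log(9) / (day[i75] - day[i25]) else 0.5
  ifz <- which(pct > 0 & pct < a0)[1L]
  b0 <- if (!is.na(ifz)) (a0 / pct[ifz] - 1) * exp(c0 * day[ifz]) else 15
  b0 <- min(max(b0, 1e-3), 1e6)
  starts <- list(c(a = a0, b = b0, c = c0),
                 c(a = a0, b = b0 * 3, c = c0 * 0.5),
                 c(a = a0 * 1.05, b = b0 / 3, c = c0 * 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(pct ~ a / (1 + b * exp(-c * day)),
                        start = as.list(st),
                        lower = c(a = 1e-6, b = 1e-9, c = 1e-9),
                        control = minpack.lm::nls.lm.control(
                          ftol = ftol, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) {
    return(new_sigmoid_fit(a = NA_real_, b = NA_real_, c = NA_real_,
                           r2 = NA_real_, converged = FALSE,
                           degenerate = FALSE, n = length(day),
                           source = source))
  }
  cf <- coef(best$fit)
  r2 <- 1 - best$dev / sum((pct - mean(pct))^2)
  new_sigmoid_fit(a = unname(cf["a"]), b = unname(cf["b"]),
                  c = unname(cf["c"]), r2 = r2, converged = TRUE,
                  degenerate = FALSE, n = length(day), source = source)
}

new_sigmoid_fit <- function(a, b, c, r2, converged, degenerate, n, source) {
  structure(list(a = a, b = b, c = c, r2 = r2, converged = converged,
                 degenerate = degenerate, n = n, source = source),
            class = "sigmoid_fit")
}

no_germination_error <- function(msg) {
  structure(class = c("thermogerm_no_germination", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Logistic germination fit: y = a / (1 + b exp(-c t))\n")
  cat(sprintf("  a = %.4g %%, b = %.4g, c = %.4g 1/day, r2 = %.4f\n",
              x$a, x$b, x$c, x$r2))
  if (x$degenerate) cat("  [degenerate: saturated course, rate unresolved]\n")
  if (!x$converged && !x$degenerate) cat("  [did not converge]\n")
  invisible(x)
}

#' Evaluate a logistic germination fit
#'
#' @param fit A [fit_sigmoid()] object (or list with `a`, `b`, `c`).
#' @param day Days at which to evaluate, vectorised.
#' @return Cumulative germination percentage at `day`.
#' @export
sigmoid_value <- function(fit, day) {
  fit$a / (1 + fit$b * exp(-fit$c * day))
}

#' Scale germination percentages to the lot maximum
#'
#' The maximum final germination percentage observed in any temperature
#' or replicate of the seed lot is taken as 100% germination; every
#' percentage is multiplied by `100 / max`. The available percentile
#' subpopulations are the deciles 10, 20, ... up to the largest multiple
#' of 10 not exceeding the minimum over temperatures of the
#' replicate-mean scaled final percentage (capped at `percentile_cap`).
#'
#' @param timecourses Long-format census data frame (see
#'   [simulate_population()] for the columns).
#' @param percentile_cap Largest percentile ever considered (default 80).
#' @return List of class `germination_scaling` with elements `factor`
#'   (scaling factor), `max_observed_pct`, `percentiles` (available
#'   deciles, possibly empty), and `finals` (per temperature x replicate
#'   raw and scaled final percentages).
#' @examples
#' cfg <- simulation_config(rng_seed = 7)
#' sc <- scale_to_max(simulate_population(cfg))
#' sc$percentiles
#' @export
scale_to_max <- function(timecourses, percentile_cap = 80) {
  tc <- validate_timecourses(timecourses)
  key <- interaction(tc$temperature_C, tc$replicate, drop = TRUE)
  finals <- do.call(rbind, lapply(split(tc, key), function(d) {
    d <- d[order(d$day), ]
    data.frame(temperature_C = d$temperature_C[1L],
               replicate = d$replicate[1L],
               final_pct = 100 * d$cumulative_germinated[nrow(d)] / d$n_seeds[1L])
  }))
  rownames(finals) <- NULL
  max_obs <- max(finals$final_pct)
  if (max_obs == 0)
    stop(no_germination_error("no germination in any treatment or replicate"))
  factor <- 100 / max_obs
  finals$scaled_pct <- finals$final_pct * factor
  by_temp <- tapply(finals$scaled_pct, finals$temperature_C, mean)
  min_scaled <- min(by_temp)
  top <- min(percentile_cap, 10 * floor(min_scaled / 10))
  percentiles <- if (top >= 10) seq(10, top, by = 10) else numeric(0)
  structure(list(factor = factor, max_observed_pct = max_obs,
                 percentiles = percentiles, finals = finals),
            class = "germination_scaling")
}

#' @export
print.germination_scaling <- function(x, ...) {
  cat(sprintf("Germination scaling: max observed %.2f%% -> factor %.4f\n",
              x$max_observed_pct, x$factor))
  cat("  available percentiles:",
      if (length(x$percentiles)) paste(x$percentiles, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Time for a fitted time course to reach a germination percentage
#'
#' Closed-form inversion of the logistic fit:
#' \eqn{t = -\ln((a/y - 1)/b) / c}.
#'
#' @param fit A converged, non-degenerate [fit_sigmoid()] object.
#' @param y Target cumulative germination percentage (raw scale, i.e.
#'   percent of sown seeds), with `0 < y < a`.
#' @return Time in days (>= 0).
#' @examples
#' fit <- list(a = 100, b = 20, c = 0.5)
#' time_to_percentile(fit, 50)  # log(20) / 0.5
#' @export
time_to_percentile <- function(fit, y) {
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) || y <= 0)
    stop("target percentage y must be a single positive number")
  if (is.na(fit$a) || is.na(fit$b) || is.na(fit$c))
    stop("fit has no usable (a, b, c) parameters")
  if (y >= fit$a)
    stop(structure(class = c("thermogerm_percentile_unreachable",
                             "error", "condition"),
                   list(message = sprintf(
                     "percentage %.3f not reachable (asymptote a = %.3f)",
                     y, fit$a), call = sys.call(-1))))
  t <- -log((fit$a / y - 1) / fit$b) / fit$c
  if (t < 0)
    stop("target percentage lies below the fitted intercept (negative time)")
  t
}

#' Germination rate as reciprocal time
#'
#' @param t Time to reach a percentile (days, positive); vectorised.
#' @return Rate in 1/day.
#' @export
germination_rate <- function(t) {
  if (any(!is.finite(t) | t <= 0)) stop("time must be positive and finite")
  1 / t
}

#' Lag time of a germination time course
#'
#' Days from sowing to the first census with a nonzero cumulative count.
#'
#' @param day Census days.
#' @param count Cumulative germinated counts.
#' @return First day with `count > 0`, or `NA` if nothing germinated.
#' @export
lag_time <- function(day, count) {
  stopifnot(length(day) == length(count))
  i <- which(count > 0)[1L]
  if (is.na(i)) NA_real_ else day[i]
}

#' Arcsine square-root transform of a percentage
#'
#' Variance-stabilising transform applied to final germination
#' percentages before ANOVA.
#'
#' @param p Percentage in \[0, 100\]; vectorised.
#' @return \eqn{\arcsin\sqrt{p/100}} in radians.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 100))
    stop("p must lie in [0, 100]")
  asin(sqrt(p / 100))
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Compares group means by one-way ANOVA, runs Tukey's honestly
#' significant difference test on all pairs, and summarises the pattern
#' as a compact letter display (groups sharing a letter do not differ at
#' level `alpha`), assembled with the insert-and-absorb algorithm.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (coerced to factor), same length.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `group_comparison`: list with `f_value`, `df`
#'   (numerator, denominator), `p_value`, `tukey` (data frame of pairwise
#'   differences and adjusted p), `letters` (named character vector, one
#'   entry per group, ordered by decreasing mean), `alpha`.
#' @examples
#' cmp <- compare_groups(c(1, 2, 3, 7, 8, 9), rep(c("low", "high"), each = 3))
#' cmp$f_value   # 54
#' cmp$letters
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), is.numeric(values))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("need at least 2 values per group")
  means <- tapply(values, groups, mean)
  ord <- names(sort(means, decreasing = TRUE))
  if (stats::var(values) == 0) {
    letters <- setNames(rep("a", nlevels(groups)), ord)
    return(structure(list(f_value = NA_real_, df = c(nlevels(groups) - 1L,
                                                     length(values) - nlevels(groups)),
                          p_value = NA_real_, tukey = NULL,
                          letters = letters, alpha = alpha),
                     class = "group_comparison"))
  }
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(pair = rownames(tk), tk, row.names = NULL)
  sig <- rownames(tk)[tk[, "p adj"] < alpha & !is.na(tk[, "p adj"])]
  sig_pairs <- strsplit(sig, "-", fixed = TRUE)
  letters <- cld_insert_absorb(ord, sig_pairs)
  structure(list(f_value = tab[["F value"]][1L],
                 df = c(tab$Df[1L], tab$Df[2L]),
                 p_value = tab[["Pr(>F)"]][1L],
                 tukey = tukey, letters = letters, alpha = alpha),
            class = "group_comparison")
}

# Compact letter display by insert-and-absorb: start from one class
# holding every level; for each significantly different pair split any
# class containing both; absorb classes that became subsets of others.
cld_insert_absorb <- function(levels_ordered, sig_pairs) {
  classes <- list(levels_ordered)
  for (pr in sig_pairs) {
    i <- pr[[1L]]; j <- pr[[2L]]
    k <- 1L
    while (k <= length(classes)) {
      cl <- classes[[k]]
      if (all(c(i, j) %in% cl)) {
        classes[[k]] <- setdiff(cl, i)
        classes <- append(classes, list(setdiff(cl, j)), after = k)
        k <- k + 1L
      }
      k <- k + 1L
    }
    # absorb subsets
    drop <- logical(length(classes))
    for (k in seq_along(classes)) {
      for (m in seq_along(classes)) {
        if (k == m || drop[m]) next
        if (all(classes[[k]] %in% classes[[m]]) &&
            (length(classes[[k]]) < length(classes[[m]]) || k > m)) {
          drop[k] <- TRUE
          break
        }
      }
    }
    classes <- classes[!drop]
  }
  out <- setNames(rep("", length(levels_ordered)), levels_ordered)
  for (k in seq_along(classes)) {
    for (lv in classes[[k]]) out[lv] <- paste0(out[lv], letters[k])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_value, x$p_value))
  cat("Tukey letters (alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}
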