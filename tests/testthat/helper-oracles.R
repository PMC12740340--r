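# Independent brute-force oracles, kept deliberately separate from the
# package's numeric machinery: direct formula evaluation on dense grids,
# finite differences from first principles.

# the asymmetric peak curve, written out directly
oracle_peak_curve <- function(x, a, b, c, d) {
  a * exp(-b * (x / c - 1)^2 + 1 / (x - d))
}

# tangent-based cardinal estimates from a dense-grid scan: derivative as
# forward differences at cell midpoints, inflections as the grid argmax /
# argmin of that derivative on either side of the curve maximum, tangents
# drawn explicitly through the midpoint values.
oracle_tangent_cardinals <- function(a, b, c, d, lower, step = 1e-5) {
  xs <- seq(lower, d - 1e-4, by = step)
  f <- oracle_peak_curve(xs, a, b, c, d)
  fp <- diff(f) / step
  mid <- xs[-length(xs)] + step / 2
  ipk <- which.max(f)
  asc <- which(mid < xs[ipk])
  dsc <- which(mid > xs[ipk])
  i_up <- asc[which.max(fp[asc])]
  i_dn <- dsc[which.min(fp[dsc])]
  tangent <- function(i) {
    x0 <- mid[i]
    s <- fp[i]
    y0 <- (f[i] + f[i + 1]) / 2
    ord <- y0 - s * x0
    list(x = x0, y = y0, slope = s, ord = ord, x_intercept = -ord / s)
  }
  up <- tangent(i_up)
  dn <- tangent(i_dn)
  list(x_max = up$x, x_min = dn$x,
       Tb = up$x_intercept, Tc = dn$x_intercept,
       Ttsub = 1 / up$slope, Ttsup = 1 / abs(dn$slope))
}

# exact logistic census data for sigmoid-fit recovery checks
make_logistic_counts <- function(a, b, c, days = 1:30, n_seeds = 100) {
  pct <- a / (1 + b * exp(-c * days))
  list(day = days, count = pct * n_seeds / 100, n_seeds = n_seeds)
}

# a small but fully analyzable simulated study (used by several files)
small_study_config <- function(seed = 101, ...) {
  simulation_config(n_seeds = 50, n_replicates = 3, rng_seed = seed, ...)
}
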