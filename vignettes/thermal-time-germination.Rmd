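---
title: "Thermal-time modelling of seed germination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time modelling of seed germination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(thermogerm)
```

## The model

Thermal-time theory describes a seed lot as a population of individuals
indexed by a percentile threshold $g$. Below the optimal temperature
$T_o$, the germination rate of the $g$-th percentile (the reciprocal of
its time to germination, in day$^{-1}$) rises linearly from the shared
base temperature $T_b$:

$$GR_{sub}(g, T) = \frac{T - T_b}{\theta_{sub}(g)},$$

and above the optimum it falls linearly to the ceiling temperature
$T_c$:

$$GR_{sup}(g, T) = \frac{T_c - T}{\theta_{sup}(g)},$$

where $\theta_{sub}$ and $\theta_{sup}$ are the sub- and supraoptimal
thermal times (degree-days, °C day) of that percentile. The quantities
of interest are the cardinal temperatures $T_b$, $T_o$, $T_c$, the
thermal times per percentile, and the slope of the linear relation
between percentile and thermal time, which summarises how much extra
thermal input each additional cohort of the lot requires.

## The estimation chain

The package estimates these quantities from cumulative germination
counts recorded daily along a temperature gradient, in five steps.

1. **Logistic time-course fits.** Each (temperature, replicate) course
   is fitted with $y(t) = a/(1 + b e^{-ct})$ by Levenberg–Marquardt
   least squares (`fit_sigmoid()`). Fits are per replicate, so that
   downstream summaries carry honest replicate-to-replicate spread
   (mean ± SD, $n$ = number of replicates).
2. **Percentile scaling.** The maximum final percentage observed in any
   treatment or replicate of a lot is taken as 100 % germination
   (`scale_to_max()`); percentile subpopulations 10 %, 20 %, … are
   expressed on that scale. The available deciles run up to the largest
   multiple of 10 not exceeding the minimum, over temperatures, of the
   replicate-mean scaled final percentage, so every retained percentile
   is observable at every temperature. Because the factor is shared,
   fitting raw percentages and scaling afterwards is equivalent to
   fitting scaled ones; $r^2$ is reported on the raw scale.
3. **Times, rates.** The logistic is inverted in closed form,
   $t = -\ln((a/y - 1)/b)/c$ (`time_to_percentile()`), and rates are
   reciprocal times. Percentiles above a replicate's fitted asymptote
   are skipped for that replicate.
4. **Peak fits and tangent cardinals.** For each (percentile,
   replicate), rate versus temperature is fitted with the asymmetric
   peak function
   $$GR(T) = a\,\exp\!\Big(-b\big(\tfrac{T}{c}-1\big)^2 + \tfrac{1}{T-d}\Big),$$
   where $a$ is the maximal rate, $b$ a $1/\sigma^2$-like width, $c$
   the temperature of the maximum and $d$ the abscissa intercept of the
   descending limb (the $1/(T-d)$ term forces $GR \to 0$ as
   $T \to d^-$). Tangents at the curve's two inflection points are
   extrapolated to the abscissa: with $y$, $s$, $x$ the rate, slope and
   temperature at an inflection, the intercept is $ORD = y - sx$, then
   $T_b = -ORD_{max}/s_{max}$, $T_c = -ORD_{min}/s_{min}$, and the
   thermal times are reciprocal tangent slopes, $\theta_{sub} =
   1/s_{max}$, $\theta_{sup} = 1/|s_{min}|$ (`tangent_cardinals()`).
5. **Percentile–thermal-time regressions and comparisons.** Percentile
   is regressed on thermal time per replicate
   (`percentile_tt_regression()`); lots and percentiles are compared by
   one-way ANOVA with Tukey HSD and a compact letter display
   (`compare_groups()`), with final percentages arcsine-square-root
   transformed where appropriate.

### Why this reading of the peak function

Typeset renderings of the peak equation are ambiguous. The form above
is the unique reading consistent with all the stated parameter
meanings: $a$ is the maximal rate (up to the small tail correction),
$c$ the temperature of the maximum, and $d$ an abscissa intercept only
if the rate genuinely collapses there, which $\exp(1/(T-d))$ provides.
The form lives in one function (`peak_function()`) so an alternative
reading would be a one-line change.

### Numerical choices

- Nonlinear least squares uses Levenberg–Marquardt (`minpack.lm`), sum
  of squares tolerance $10^{-10}$, with small multistart grids: three
  jittered initialisations for the logistic, four $(b_0, d_0)$ pairs
  for the peak. The lowest-deviance converged solution is kept;
  solutions violating the validity constraint $c < d$ are rejected.
  Non-convergent and degenerate (saturated-course) fits are flagged and
  excluded from downstream means, and every exclusion is logged.
- Derivatives of the peak curve are central differences with step
  $10^{-5}$ °C, robust to swapping the functional form. Inflection
  points are bracketed on a dense grid (step $10^{-3}$ °C) and refined
  by golden-section/Brent search; a brute-force grid scan at
  $10^{-5}$ °C serves as the independent oracle in the test suite.
- The ascending-limb inflection search starts 5 °C below the coldest
  observed temperature; extrema landing on a search boundary are
  flagged.
- Degenerate inputs error early with typed conditions (all-zero
  courses, unreachable percentiles, zero tangent slopes, constant
  thermal times).

## The synthetic-data generator

Raw thermogradient germination records are rarely redistributable, so
the generator (`simulate_population()`) is a first-class module: it implements exactly the population-threshold
model the estimator assumes, which makes end-to-end parameter recovery
a meaningful test of the whole chain.

- Percentile thresholds are uniform on (0, 100) — the scaled empirical
  percentile construction implies a uniform threshold distribution, and
  it keeps $\theta(g)$ exactly the inverse of the percentile-versus-
  thermal-time linear fits: $\theta_{sub}(g) = \theta_{sub,50} +
  (g-50)/s_{sub}$ and $\theta_{sup}(g) = \theta_{sup,50} -
  (g-50)/s_{sup}$.
- Viability is binomial per seed; non-viable seeds never germinate.
  Scaling to the observed maximum undoes viability in expectation,
  which is precisely the role the percentile scaling plays in the
  analysis.
- Recording is a daily census: the germination day is the ceiling of
  the continuous time $lag + 1/GR$ (the optional fixed physiological
  lag defaults to 0, as no separate lag is identifiable from daily
  counts). Seeds whose time exceeds the 30-day recording period never
  appear.
- The sub- and supraoptimal branches are generated independently, as
  they are fitted; no continuity at $T_o$ is imposed by the model.
- One RNG stream per run, seeded from the configuration; temperatures
  and replicates are drawn in a fixed order, so seeded runs are
  byte-for-byte reproducible.

**Default scenario.** Five replicates of 50 seeds at 9 temperatures
(11–33 °C), daily censusing for 30 days, $T_b = 10.5$ °C, $T_c =
35$ °C, $\theta_{sub,50} = 60$ °C day, percentile slopes 2.5 and
15 % (°C day)$^{-1}$, viability 0.9 — a thermophilic pioneer-tree lot
on a laboratory thermogradient. $T_o$ is set to 29.5 °C, the midpoint
of the 28–31 °C interval in which such lots show their fastest
germination. $\theta_{sup,50} = 17.4$ °C day is chosen so the median
seed's rate law is continuous at the optimum: field reports of
supraoptimal thermal times of only 4–7 °C day are *tangent-method
outputs*, and taking such a value as a generating secant would make the
true rate jump about three-fold at $T_o$ — a physically implausible
spike at which the peak-function fit degenerates (the fitted maximum
migrates past the descending intercept). Users can still set any
$\theta_{sup,50}$ in `simulation_config()`.

**What the generator does not emulate.** Real lots violate the shared-
$T_b$ assumption at the gradient's cold edge (slow germination is
observed at temperatures where a single-$T_b$ thermal-time model
predicts none within the recording period); there is no seed-to-seed
noise beyond the threshold distribution, no dormancy, no mortality of
non-germinated seeds, and no water-potential (hydrothermal) dimension.
Passing recovery tests therefore validates the estimation chain under
the model's own assumptions, not the model's adequacy for any real lot.

## Estimator bias under the recovery tests

The generating rate law is piecewise linear in temperature while the
estimator fits a smooth peak function and takes tangents at its
inflection points. On near-linear limbs the steepest tangent of the
fitted curve is steeper than the limb itself, and on the descending
side the least-squares $d$ settles below the true intercept because the
peak family bends under a straight descent. The recovery tests measure
the consequence under the default design: the grand-mean base
temperature comes out roughly 1.5 °C above the generating value, the
ceiling roughly 1.3 °C below it, and $\theta_{sub,50}$ about 12 % low,
with the percentile-versus-thermal-time *slope* essentially unbiased
(the compression is mostly a level shift). This bias is a property of
the tangent-extrapolation method itself — it persists when the
estimator is applied to exact, noise-free piecewise-linear rates — and
should be kept in mind when comparing tangent-based cardinal estimates
with bilinear-regression ones from other studies.

## Degree-days and field timing

`accumulate_degree_days()` integrates the excess of logged soil
temperature above $T_b$, clipped at $T_o$, over a diurnal window
(default 08–18 h), weighting each reading by its full sampling interval
(left-closed rule), and divides the °C h total by 24 to express °C day
per calendar day. Days with incomplete in-window coverage are dropped,
never imputed. The clipped-excess integrand is the standard degree-day
definition and the one commensurable with thermal times estimated as
reciprocal rate slopes; the alternative reading (summing raw
temperatures that lie between $T_b$ and $T_o$) is available via
`convention = "raw"`, because published cumulative-temperature figures
cannot always be reconciled with a single convention. Division by 24
(not by window length) is likewise a choice surfaced in the interface
rather than hard-coded arithmetic downstream:
`days_to_thermal_time(target, daily_units)` accepts any data-derived
daily accumulation.

The elevational lapse model $Y = a + b x^3$ (`fit_lapse()`) is fitted
by ordinary least squares on $x^3$, and the endpoint rate
$\Delta T / (\Delta \mathrm{elevation}/100)$ is reported alongside, in
°C per 100 m.

## Problem sizes

The test-suite simulations use the default study design (9
temperatures × 5 replicates × 50 seeds) or smaller 3-replicate
variants; the parameter-recovery property runs ten seeded repetitions
of the full design, and the grid oracle for the tangent construction
scans 50 random peak curves at $10^{-5}$ °C resolution. These sizes
keep every property estimable with comfortable Monte-Carlo margins.

## Limitations

- Germination times are interval-censored by the daily census; the
  logistic inversion ignores the censoring (as the underlying method
  does). A survival-analysis treatment is out of scope.
- Tangent-based cardinal estimates carry the structural bias described
  above; no bilinear/broken-stick alternative estimator is provided.
- The degree-day module does no gap-filling or microclimate modelling;
  logger traces must be equally spaced.
- Published supraoptimal thermal times and cumulative-temperature
  values mix conventions; both degree-day conventions and the target
  thermal time are therefore explicit inputs.
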