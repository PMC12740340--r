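# thermogerm

Thermal-time modelling of seed germination across temperature
gradients: cardinal temperatures, thermal times per percentile
subpopulation, and degree-day prediction of field germination timing.

## The problem

Seed ecophysiologists characterise a seed lot's temperature response by
incubating replicates along a gradient of constant temperatures and
recording cumulative germination daily. Thermal-time theory summarises
the outcome with three cardinal temperatures — base (*T*<sub>b</sub>,
below which nothing germinates), optimal (*T*<sub>o</sub>, fastest) and
ceiling (*T*<sub>c</sub>, above which nothing germinates) — and with
thermal times θ (°C day): below the optimum, the *g*-th percentile of
the lot germinates when the accumulated excess temperature
(*T* − *T*<sub>b</sub>) · *t* reaches θ<sub>sub</sub>(*g*), so its
germination rate (reciprocal days) is
*GR* = (*T* − *T*<sub>b</sub>)/θ<sub>sub</sub>(*g*); above the optimum,
*GR* = (*T*<sub>c</sub> − *T*)/θ<sub>sup</sub>(*g*). These parameters
predict germination timing anywhere a soil-temperature record exists,
which makes them practical tools for restoration planting and for
assessing how species will respond to warming.

`thermogerm` implements one complete estimation chain:

1. logistic fits *y* = *a*/(1 + *b* e<sup>−*ct*</sup>) to each
   cumulative time course (`fit_sigmoid()`), inverted in closed form to
   times-to-percentile (`time_to_percentile()`), after scaling
   percentages to the lot-wide observed maximum (`scale_to_max()`);
2. an asymmetric peak fit of rate versus temperature per percentile and
   replicate,
   *GR*(*T*) = *a* exp(−*b*(*T*/*c* − 1)² + 1/(*T* − *d*))
   (`fit_peak()`); tangents at its two inflection points are
   extrapolated to the abscissa to give *T*<sub>b</sub> (ascending
   limb) and *T*<sub>c</sub> (descending limb), with the thermal times
   as reciprocal tangent slopes (`tangent_cardinals()`);
3. linear regressions of percentile on thermal time
   (`percentile_tt_regression()`) and ANOVA + Tukey compact-letter
   comparisons (`compare_groups()`);
4. degree-day accumulation from soil logger traces over a diurnal
   window, clipped between *T*<sub>b</sub> and *T*<sub>o</sub>
   (`accumulate_degree_days()`), and days-to-target prediction
   (`days_to_thermal_time()`), plus a cubic elevational lapse model
   (`fit_lapse()`);
5. seed-biochemistry arithmetic: fatty-acid totals, the
   saturated:unsaturated ratio, and oil-free water content.

A population-threshold simulator (`simulate_population()`,
`simulate_soil_trace()`) generates germination time courses and logger
traces with known parameters, so the whole chain is validated by
parameter recovery; `run_pipeline()` chains every stage and writes tidy
CSV tables. See the vignette
(`vignettes/thermal-time-germination.Rmd`) for the model, the numerical
choices and the estimator's known biases.

## Worked example

Simulate one seed lot under the default study design (9 temperatures
11–33 °C, 5 replicates × 50 seeds, daily censusing for 30 days, true
*T*<sub>b</sub> 10.5 °C, *T*<sub>c</sub> 35 °C, θ<sub>sub,50</sub>
60 °C day) and run the full analysis:

```r
library(thermogerm)

cfg <- simulation_config(rng_seed = 42)
tc  <- simulate_population(cfg, elevation = 2345)
res <- analyze_thermal_time(tc)
res
#> Thermal-time analysis
#>   40 logistic fits, 38 cardinal estimates, 3 exclusions
#>   grand means: Tb 11.94 degC, Tc 33.69 degC

agg <- aggregate_cardinals(res$cardinals)
round(agg[, c("percentile", "n", "Tb_C_mean", "Tb_C_sd",
              "Tc_C_mean", "Ttsub_Cday_mean")], 2)
#>   percentile n Tb_C_mean Tb_C_sd Tc_C_mean Ttsub_Cday_mean
#> 1         10 5     12.17    0.94     33.66           35.90
#> 2         20 5     12.04    0.70     33.67           41.89
#> 3         30 5     11.98    0.61     33.68           45.93
#> 4         40 5     11.93    0.56     33.69           49.32
#> 5         50 5     11.90    0.55     33.69           52.53
#> 6         60 5     11.87    0.55     33.70           55.91
#> 7         70 5     11.85    0.58     33.70           59.93
#> 8         80 3     11.72    0.63     33.76           64.68
```

Each row is one percentile subpopulation: mean ± SD over replicate-wise
tangent estimates (*n* = replicates with a usable peak fit). The
recovered base temperature sits ~1.4 °C above and the ceiling ~1.3 °C
below the generating values — the structural bias of the
tangent-at-inflection construction on piecewise-linear rate data, which
the recovery tests quantify and the vignette explains. The 50th
percentile's suboptimal thermal time (52.5 °C day) feeds the field
prediction:

```r
tr <- simulate_soil_trace(mean = 22, amplitude = 8, noise_sd = 0.5,
                          days = 7, interval = 30, rng_seed = 42)
dd <- accumulate_degree_days(tr, t_b = mean(res$cardinals$Tb_C),
                             t_o = 29, window = c(8, 18))
dd
#> Degree-days (excess, window 8-18 h, Tb 11.94, To 29.00):
#>   6.39 +/- 0.04 degC day/day over 7 day(s)

p50 <- res$cardinals[res$cardinals$percentile == 50, ]
days_to_thermal_time(mean(p50$Ttsub_Cday), dd$mean)
#> [1] 8.22
```

So under this (simulated) early-season soil regime, half of the scaled
maximum germination would need about 8 days of diurnal degree-day
accumulation. Biochemistry helpers work on the built-in reference
profiles:

```r
fa <- fatty_acid_table()
total_fatty_acids(fa[fa$elevation_m == 2500, ])["total_pct"]  # 55.747 %
sat_unsat_ratio(fa[fa$elevation_m == 2500, ])                 # 0.136
oil_free_water_content(16.84, 30.816)                         # 24.34 %
```

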