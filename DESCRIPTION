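Package: thermogerm
Title: Thermal-Time Modelling of Seed Germination Across Temperature
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates cardinal temperatures (base, optimal, ceiling) and
    sub- and supraoptimal thermal times of seed lots from cumulative
    germination time courses recorded along a temperature gradient.
    Cumulative germination is fitted to logistic curves and inverted to
    times-to-percentile; germination rates are fitted to an asymmetric
    peak function of temperature whose inflection-point tangents are
    extrapolated to the base and ceiling temperatures, with thermal times
    taken as reciprocal tangent slopes. Also accumulates degree-days from
    soil-temperature logger traces over a diurnal window to predict field
    germination timing, fits elevational lapse models, summarises seed
    fatty-acid profiles, and ships a population-threshold simulator of
    germination time courses for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
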