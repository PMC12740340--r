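#' Total fatty-acid content of a seed-oil profile
#'
#' Sums the five measured fatty acids (palmitic, linoleic, oleic,
#' stearic, nonadecilic; mg per g fresh seed) and converts the total to
#' percent of fresh mass (mg/g divided by 10).
#'
#' @param profile One row of a fatty-acid table (see
#'   [fatty_acid_table()]) or a named list/vector with the five
#'   `*_mg_g` concentrations.
#' @return Named numeric vector `total_mg_g`, `total_pct`.
#' @examples
#' fa <- fatty_acid_table()
#' total_fatty_acids(fa[fa$elevation_m == 2500, ])  # 55.747 %
#' @export
total_fatty_acids <- function(profile) {
  x <- acid_concentrations(profile)
  total <- sum(x)
  c(total_mg_g = total, total_pct = total / 10)
}

acid_concentrations <- function(profile) {
  acids <- c("palmitic_mg_g", "linoleic_mg_g", "oleic_mg_g",
             "stearic_mg_g", "nonadecilic_mg_g")
  if (!all(acids %in% names(profile)))
    stop("profile must contain: ", paste(acids, collapse = ", "))
  x <- vapply(acids, function(a) as.numeric(profile[[a]][1L]), numeric(1))
  if (any(!is.finite(x) | x < 0))
    stop("fatty-acid concentrations must be finite and non-negative")
  x
}

#' Saturated to unsaturated fatty-acid ratio
#'
#' Ratio of saturated (palmitic + stearic) to unsaturated (linoleic +
#' oleic) fatty-acid concentrations. Nonadecilic acid, although
#' chemically saturated, is excluded from the numerator by default (it
#' is a trace constituent reported separately from the conventional
#' ratio); set `include_nonadecilic = TRUE` to count it.
#'
#' @inheritParams total_fatty_acids
#' @param include_nonadecilic Count nonadecilic acid as saturated.
#' @return The dimensionless ratio.
#' @examples
#' fa <- fatty_acid_table()
#' sat_unsat_ratio(fa[fa$elevation_m == 2500, ])  # 0.136
#' @export
sat_unsat_ratio <- function(profile, include_nonadecilic = FALSE) {
  x <- acid_concentrations(profile)
  unsat <- x[["linoleic_mg_g"]] + x[["oleic_mg_g"]]
  if (unsat <= 0) stop("unsaturated fatty-acid sum must be positive")
  sat <- x[["palmitic_mg_g"]] + x[["stearic_mg_g"]] +
    if (include_nonadecilic) x[["nonadecilic_mg_g"]] else 0
  sat / unsat
}

#' Oil-free seed water content on a fresh basis
#'
#' Re-expresses the fresh-basis water content relative to the non-lipid
#' fresh mass: \eqn{WC_{of} = 100 \, WC_{fb} / (100 - LC_{fb})}.
#'
#' @param wc_fb Water content, percent fresh basis, in \[0, 100\].
#' @param lc_fb Total lipid content, percent fresh basis, in \[0, 100).
#' @return Oil-free water content in percent.
#' @examples
#' oil_free_water_content(16.84, 30.816)  # 24.34 %
#' @export
oil_free_water_content <- function(wc_fb, lc_fb) {
  stopifnot(is.numeric(wc_fb), is.numeric(lc_fb))
  if (any(!is.finite(wc_fb) | wc_fb < 0 | wc_fb > 100))
    stop("wc_fb must lie in [0, 100]")
  if (any(!is.finite(lc_fb) | lc_fb < 0 | lc_fb >= 100))
    stop("lc_fb must lie in [0, 100)")
  100 * wc_fb / (100 - lc_fb)
}
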