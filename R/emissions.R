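#' Trapezoid integration weights for a sampling schedule
#'
#' The weight vector `w` such that `sum(w * f)` equals the trapezoidal
#' approximation of the integral of a flux series `f` observed at `dates`:
#' end weights are half the adjacent interval, interior weights half the
#' span between neighbours, and the weights sum to the monitoring span
#' `t_n - t_1`. These are exactly the contrast coefficients used to turn
#' per-date model means into cumulative emissions.
#'
#' @param dates Numeric sampling dates (>= 2, strictly increasing, no
#'   ties).
#' @return Numeric weight vector of `length(dates)`.
#' @examples
#' trapezoid_weights(c(0, 1, 3))
#' @export
trapezoid_weights <- function(dates) {
  if (length(dates) < 2) abort("At least 2 dates are needed.")
  if (any(diff(dates) <= 0)) abort("`dates` must be strictly increasing (no ties).")
  n <- length(dates)
  w <- numeric(n)
  w[1] <- (dates[2] - dates[1]) / 2
  w[n] <- (dates[n] - dates[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (dates[3:n] - dates[1:(n - 2)]) / 2
  w
}

#' Cumulative N2O emission of one plot's flux series
#'
#' Trapezoidal integration of a per-plot flux time series over the
#' monitoring window, converted to kg N2O-N per hectare. Supported flux
#' units: `"ug_n_m2_h"` (micrograms N2O-N per m^2 per hour, the chamber
#' scale) and `"g_n_ha_d"` (grams N2O-N per hectare per day).
#'
#' @param series A data frame with columns `date` (numeric days, strictly
#'   increasing) and `flux`.
#' @param flux_unit Unit tag of the flux column (required; no default
#'   conversion is guessed).
#' @return Cumulative emission in kg N2O-N ha^-1 (scalar).
#' @examples
#' s <- tibble::tibble(date = c(0, 30, 60), flux = 10)
#' cumulative_emission(s, "ug_n_m2_h") # 0.144 kg N ha^-1
#' @seealso [cumulate_emissions()] for many plots at once.
#' @export
cumulative_emission <- function(series, flux_unit = c("ug_n_m2_h", "g_n_ha_d")) {
  check_columns(series, c("date", "flux"))
  if (missing(flux_unit)) abort("`flux_unit` must be given ('ug_n_m2_h' or 'g_n_ha_d').")
  flux_unit <- match.arg(flux_unit)
  w <- trapezoid_weights(series$date) # days
  raw <- sum(w * series$flux)
  switch(flux_unit,
    # ug m^-2 h^-1 * d -> * 24 h/d * 1e4 m2/ha * 1e-9 kg/ug
    ug_n_m2_h = raw * 24 * 1e4 * 1e-9,
    # g ha^-1 d^-1 * d -> kg
    g_n_ha_d = raw / 1000
  )
}

#' Cumulative emissions for every plot in a campaign table
#'
#' @param flux_table Long table with columns `plot_id`, `date`, `flux`,
#'   and optionally `treatment`/`year` (carried through).
#' @inheritParams cumulative_emission
#' @return A tibble with one row per plot: ids plus `cum_kg_n_ha`.
#' @export
cumulate_emissions <- function(flux_table, flux_unit = c("ug_n_m2_h", "g_n_ha_d")) {
  check_columns(flux_table, c("plot_id", "date", "flux"))
  flux_unit <- match.arg(flux_unit)
  ids <- intersect(c("plot_id", "treatment", "year"), names(flux_table))
  flux_table %>%
    group_by(dplyr::across(dplyr::all_of(ids))) %>%
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$date), , drop = FALSE]
      tibble(cum_kg_n_ha = cumulative_emission(df[, c("date", "flux")], flux_unit))
    }) %>%
    ungroup()
}

#' Area-based N2O emission factor
#'
#' Fraction of the nitrogen input emitted as N2O-N after subtracting the
#' emission of a zero-N background treatment:
#' `(cum - background) / n_input`. Negative values are reported as such
#' (a treatment can emit less than the background).
#'
#' @param cum Cumulative emission of the treatment (kg N2O-N ha^-1).
#' @param background Cumulative emission of the background treatment
#'   (kg N2O-N ha^-1).
#' @param n_input Nitrogen input (kg N ha^-1, > 0): catch-crop residue N
#'   plus fertilizer N as applicable.
#' @return Emission factor as a fraction; vectorized.
#' @examples
#' emission_factor(cum = 0.80, background = 0.25, n_input = 32.3)
#' @export
emission_factor <- function(cum, background, n_input) {
  if (any(n_input <= 0)) abort("`n_input` must be positive.")
  (cum - background) / n_input
}

#' Yield-scaled N2O emission factor
#'
#' Background-corrected cumulative emission per unit of nitrogen in
#' harvested plant biomass: `(cum - background) / plant_n`.
#'
#' @inheritParams emission_factor
#' @param plant_n N content of harvested above-ground biomass
#'   (kg N ha^-1, > 0).
#' @return kg N2O-N per kg plant-N; vectorized.
#' @examples
#' yield_scaled_ef(cum = 0.80, background = 0.25, plant_n = 88.8)
#' @export
yield_scaled_ef <- function(cum, background, plant_n) {
  if (any(plant_n <= 0)) abort("`plant_n` must be positive.")
  (cum - background) / plant_n
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false discovery rate control valid under arbitrary dependence:
#' sorted p-values are scaled by `m * c(m) / i` with
#' `c(m) = sum(1/(1:m))`, then enforced monotone from the largest down
#' and capped at 1. Input order is preserved in the output.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' by_fdr(c(0.01, 0.02, 0.04))
#' @export
by_fdr <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(numeric())
  }
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BY")
}
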