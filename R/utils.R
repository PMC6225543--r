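# Internal helpers shared across modules.

# Universal gas constant, J mol^-1 K^-1
.R_GAS <- 8.31446

# Grams of N per mol of N2O (two N atoms, 14 g each)
.G_N_PER_MOL_N2O <- 28

#' Mass of N2O-N per cubic metre of air per ppb of mixing ratio
#'
#' Ideal-gas conversion: 1 ppb of N2O corresponds to
#' `1e-9 * P / (R * T)` mol N2O per m^3 of air, i.e.
#' `28e-9 * P / (R * T)` g N2O-N per m^3.
#'
#' @param temp_c Air temperature (degrees C).
#' @param pressure_kpa Air pressure (kPa); defaults to one standard atmosphere.
#' @return Micrograms of N2O-N per m^3 per ppb.
#' @examples
#' ppb_to_ug_n_m3(20)
#' @export
ppb_to_ug_n_m3 <- function(temp_c, pressure_kpa = 101.325) {
  stopifnot(is.numeric(temp_c), is.numeric(pressure_kpa))
  if (any(pressure_kpa <= 0)) abort("`pressure_kpa` must be positive.")
  t_k <- temp_c + 273.15
  if (any(t_k <= 0)) abort("`temp_c` below absolute zero.")
  # 1e-9 mol fraction * mol air m^-3 * g N mol^-1 * 1e6 ug g^-1
  1e-9 * (pressure_kpa * 1000) / (.R_GAS * t_k) * .G_N_PER_MOL_N2O * 1e6
}

# Stop unless x is a data frame containing the named columns.
check_columns <- function(x, cols, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Run code under a temporary RNG seed when one is supplied; otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
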