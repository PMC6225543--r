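#' Water-filled pore space
#'
#' Total porosity is computed from bulk and particle density,
#' `Phi = 1 - rho_b / rho_s`; volumetric water content from gravimetric
#' water content, `theta_v = theta_g * rho_b` (water density 1 g cm^-3);
#' and WFPS is their ratio `theta_v / Phi`, clipped to [0, 1] with a
#' warning if a physically inconsistent input forces clipping.
#'
#' @param theta_g Gravimetric water content (g water per g dry soil, >= 0).
#' @param rho_b Dry bulk density (g cm^-3, < `rho_s`).
#' @param rho_s Particle density (g cm^-3); 2.65 is the standard
#'   mineral-soil value.
#' @return WFPS as a fraction in [0, 1]; vectorized.
#' @examples
#' wfps(theta_g = 0.178, rho_b = 1.35)
#' @seealso [soil_state()] for the full per-sample aeration table.
#' @export
wfps <- function(theta_g, rho_b, rho_s = 2.65) {
  if (any(theta_g < 0)) abort("`theta_g` must be non-negative.")
  if (any(rho_b <= 0) || any(rho_s <= 0)) abort("Densities must be positive.")
  if (any(rho_b >= rho_s)) abort("`rho_b` must be below the particle density `rho_s`.")
  phi <- 1 - rho_b / rho_s
  w <- theta_g * rho_b / phi
  if (any(w > 1)) {
    warn("WFPS above 1 clipped: water content exceeds total porosity.")
  }
  pmin(pmax(w, 0), 1)
}

#' Relative soil-gas diffusivity
#'
#' Structure-dependent water-induced linear reduction model for the ratio
#' of the gas diffusion coefficient in soil to that in free air:
#' \deqn{D_p/D_0 = \Phi^2 (\varepsilon/\Phi)^X, \quad
#'   X = 2 + \log(\varepsilon_{100}^{0.25}) / \log(\varepsilon_{100}/\Phi),}
#' where \eqn{\Phi} is total porosity, \eqn{\varepsilon} volumetric air
#' content, and \eqn{\varepsilon_{100}} the air content at -100 cm H2O
#' matric potential (all m^3 m^-3). The logarithm base cancels in the
#' ratio. The result lies in [0, \eqn{\Phi^2}].
#'
#' @param phi Total porosity (0 < `phi` < 1).
#' @param epsilon Volumetric air content (0 <= `epsilon` <= `phi`).
#' @param epsilon100 Air content at -100 cm H2O (0 < `epsilon100` < `phi`).
#' @return Dimensionless `Dp/D0`; vectorized.
#' @examples
#' relative_gas_diffusivity(phi = 0.49, epsilon = 0.3, epsilon100 = 0.15)
#' @export
relative_gas_diffusivity <- function(phi, epsilon, epsilon100) {
  if (any(phi <= 0 | phi >= 1)) abort("`phi` must lie in (0, 1).")
  if (any(epsilon < 0 | epsilon > phi)) abort("`epsilon` must lie in [0, phi].")
  if (any(epsilon100 <= 0)) abort("`epsilon100` must be positive.")
  if (any(epsilon100 == phi)) {
    abort(paste(
      "`epsilon100` equal to total porosity makes the exponent undefined",
      "(log(epsilon100/phi) = 0): the -100 cm H2O air content must be",
      "strictly below total porosity."
    ))
  }
  if (any(epsilon100 > phi)) abort("`epsilon100` must be below total porosity.")
  x <- 2 + log(epsilon100^0.25) / log(epsilon100 / phi)
  ifelse(epsilon == 0, 0, phi^2 * (epsilon / phi)^x)
}

#' Per-sample soil aeration state
#'
#' Tidy wrapper deriving porosity, volumetric water, air-filled porosity,
#' WFPS and (when `epsilon100` is available) relative gas diffusivity for
#' every row of a soil sampling table.
#'
#' @param soil A data frame with columns `theta_g` and `rho_b`, optionally
#'   `epsilon100`; any id columns (plot, date, treatment) pass through.
#' @param rho_s Particle density (g cm^-3).
#' @return The input tibble plus `phi`, `theta_v`, `epsilon`, `wfps` and
#'   `dp_d0` (`NA` when `epsilon100` is absent).
#' @examples
#' soil_state(tibble::tibble(theta_g = c(0.15, 0.20), rho_b = 1.35, epsilon100 = 0.15))
#' @export
soil_state <- function(soil, rho_s = 2.65) {
  check_columns(soil, c("theta_g", "rho_b"))
  out <- as_tibble(soil) %>%
    mutate(
      phi = 1 - .data$rho_b / rho_s,
      theta_v = .data$theta_g * .data$rho_b,
      wfps = wfps(.data$theta_g, .data$rho_b, rho_s),
      epsilon = pmax(.data$phi - .data$theta_v, 0)
    )
  out$dp_d0 <- if ("epsilon100" %in% names(out)) {
    relative_gas_diffusivity(out$phi, pmin(out$epsilon, out$phi), out$epsilon100)
  } else {
    NA_real_
  }
  out
}

#' Growing-degree-day sum
#'
#' Accumulated thermal time: `sum(max(0, T_mean - t_base))` over daily
#' mean temperatures. The base temperature is configurable; the default
#' 0 degrees C is a common convention for spring cereals, stated here as
#' this package's assumption rather than a universal standard.
#'
#' @param daily_mean_temps Daily mean air temperatures (degrees C).
#' @param t_base Base temperature (degrees C) below which no thermal time
#'   accrues.
#' @return Degree-day sum (degree C days).
#' @examples
#' growing_degree_days(c(4, -2, 6), t_base = 5)
#' @export
growing_degree_days <- function(daily_mean_temps, t_base = 0) {
  if (length(daily_mean_temps) == 0) abort("Temperature series must be non-empty.")
  sum(pmax(0, daily_mean_temps - t_base))
}
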