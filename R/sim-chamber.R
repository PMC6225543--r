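#' Simulate a static-chamber concentration-time series
#'
#' Generates one chamber deployment's headspace N2O series from the
#' Hutchinson-Mosier (HM) concentration model
#' \deqn{C(t) = \phi + (C_0 - \phi) e^{-\kappa t},}
#' where \eqn{\phi} is the asymptotic mixing ratio and \eqn{\kappa} the
#' curvature rate. The asymptote is chosen so that the flux at deployment
#' equals `f0`: in mixing-ratio units the initial slope is
#' `f0 / (h * conv)` with `conv` the ideal-gas ppb-to-mass factor at the
#' stated temperature and pressure, and \eqn{\phi = C_0 +} slope
#' \eqn{/\kappa}. In the limit `kappa = 0` the series is exactly linear,
#' `C(t) = C0 + slope * t`. Gaussian noise of standard deviation
#' `noise_sd` is added to each concentration.
#'
#' Defaults mirror a typical field deployment: 0.20 m chamber height over a
#' 0.75 x 0.75 m collar, five samples over 2 h.
#'
#' @param f0 True surface flux at deployment (ug N2O-N m^-2 h^-1).
#' @param kappa Curvature rate (h^-1, >= 0; 0 gives the linear limit).
#' @param c0 Initial mixing ratio (ppb).
#' @param h Chamber height, i.e. headspace volume per soil area (m; > 0).
#' @param noise_sd Additive concentration noise (ppb, >= 0).
#' @param times Sampling times (h since deployment), strictly increasing.
#' @param temp_c,pressure_kpa Air temperature (deg C) and pressure (kPa)
#'   used for the gas-law conversion.
#' @param chamber_id Identifier carried into the output.
#' @param seed Optional integer seed; the ambient RNG state is untouched.
#'
#' @return A tibble with one row per sampling time:
#'   `chamber_id`, `time_h`, `conc_ppb`, `h_m`, `temp_c`, `pressure_kpa`,
#'   plus the ground truth as `true_f0` and `true_kappa` for downstream
#'   recovery checks.
#' @examples
#' sim_chamber_series(f0 = 100, kappa = 0.5, noise_sd = 0)
#' @seealso [fit_hm_flux()], [fit_linear_flux()]
#' @export
sim_chamber_series <- function(f0,
                               kappa = 0,
                               c0 = 330,
                               h = 0.2,
                               noise_sd = 0,
                               times = seq(0, 2, by = 0.5),
                               temp_c = 10,
                               pressure_kpa = 101.325,
                               chamber_id = "chamber_1",
                               seed = NULL) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0) {
    abort("`kappa` must be a single non-negative number.")
  }
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    abort("`h` must be a single positive number (chamber height, m).")
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing with at least two points.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")

  conv <- ppb_to_ug_n_m3(temp_c, pressure_kpa)
  slope0 <- f0 / (h * conv) # initial slope in ppb h^-1
  conc <- if (kappa == 0) {
    c0 + slope0 * times
  } else {
    phi <- c0 + slope0 / kappa
    phi + (c0 - phi) * exp(-kappa * times)
  }
  if (noise_sd > 0) {
    conc <- conc + with_seed_if(seed, rnorm(length(times), 0, noise_sd))
  }
  tibble(
    chamber_id = chamber_id,
    time_h = as.numeric(times),
    conc_ppb = conc,
    h_m = h,
    temp_c = temp_c,
    pressure_kpa = pressure_kpa,
    true_f0 = f0,
    true_kappa = kappa
  )
}
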