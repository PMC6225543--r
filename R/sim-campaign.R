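#' Simulate a campaign of plot-level N2O flux series
#'
#' Draws per-plot, per-date fluxes from a gamma distribution with a
#' specified mean trajectory, emulating the positively skewed flux
#' distributions typical of field N2O monitoring, with an emission pulse
#' following fertilization and decay back to background. The gamma is
#' parameterized by (mean, shape), matching the mean-model view of a gamma
#' GLMM: `flux ~ Gamma(shape, scale = mean / shape)`.
#'
#' @param n_plots Number of plots (>= 0).
#' @param dates Numeric sampling dates (e.g. day of year), strictly
#'   increasing.
#' @param mean_flux Mean flux per date (ug N2O-N m^-2 h^-1); either a
#'   single positive number recycled over dates or a vector of
#'   `length(dates)` positive values.
#' @param shape Gamma shape parameter (> 0); larger values give less
#'   skewed, more nearly normal fluxes.
#' @param treatment Treatment label carried into the output.
#' @param seed Optional integer seed.
#'
#' @return A tibble `plot_id`, `treatment`, `date`, `flux` with
#'   `n_plots * length(dates)` rows (zero rows when `n_plots = 0`), flux
#'   in ug N2O-N m^-2 h^-1.
#' @examples
#' sim_flux_campaign(4, dates = c(100, 107, 114), mean_flux = c(5, 40, 10), seed = 1)
#' @seealso [cumulative_emission()], [pulse_mean_flux()]
#' @export
sim_flux_campaign <- function(n_plots,
                              dates,
                              mean_flux,
                              shape = 2,
                              treatment = "T1",
                              seed = NULL) {
  if (!is.numeric(n_plots) || length(n_plots) != 1 || n_plots < 0) {
    abort("`n_plots` must be a single non-negative integer.")
  }
  if (length(dates) < 1 || any(diff(dates) <= 0)) {
    abort("`dates` must be strictly increasing.")
  }
  if (length(mean_flux) == 1) mean_flux <- rep(mean_flux, length(dates))
  if (length(mean_flux) != length(dates)) {
    abort("`mean_flux` must have length 1 or length(dates).")
  }
  if (any(mean_flux <= 0)) abort("`mean_flux` must be positive.")
  if (shape <= 0) abort("`shape` must be positive.")
  if (n_plots == 0) {
    return(tibble(
      plot_id = character(), treatment = character(),
      date = numeric(), flux = numeric()
    ))
  }

  grid <- tidyr::expand_grid(
    plot_id = sprintf("plot_%02d", seq_len(n_plots)),
    date = as.numeric(dates)
  )
  mu <- mean_flux[match(grid$date, dates)]
  flux <- with_seed_if(seed, rgamma(nrow(grid), shape = shape, scale = mu / shape))
  tibble(
    plot_id = grid$plot_id,
    treatment = treatment,
    date = grid$date,
    flux = flux
  )
}

#' Fertilization-pulse mean-flux trajectory
#'
#' Convenience mean model for [sim_flux_campaign()]: background flux before
#' fertilization, then an exponential-decay pulse peaking shortly after the
#' fertilization date, mimicking the spring emission pattern of fertilized
#' arable soil.
#'
#' @param dates Numeric sampling dates (day of year).
#' @param fert_date Fertilization day of year.
#' @param background Background mean flux (ug N2O-N m^-2 h^-1).
#' @param pulse_height Added mean flux at the pulse peak.
#' @param decay_days e-folding time of the pulse (days).
#' @param lag_days Days between fertilization and peak emission.
#' @return Numeric vector of positive mean fluxes, one per date.
#' @examples
#' pulse_mean_flux(seq(95, 160, by = 7), fert_date = 102)
#' @export
pulse_mean_flux <- function(dates,
                            fert_date = 102,
                            background = 3,
                            pulse_height = 80,
                            decay_days = 10,
                            lag_days = 4) {
  stopifnot(background > 0, pulse_height >= 0, decay_days > 0)
  peak <- fert_date + lag_days
  pulse <- ifelse(dates < peak,
    pulse_height * pmax(0, (dates - fert_date) / lag_days),
    pulse_height * exp(-(dates - peak) / decay_days)
  )
  background + pulse
}
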