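#' Estimate chamber N2O flux by linear regression
#'
#' Ordinary least-squares slope of mixing ratio against time, converted to
#' a surface flux by the chamber height and the ideal-gas factor at the
#' deployment's temperature and pressure:
#' `f0 = slope [ppb/h] * conv [ug N m^-3 / ppb] * h [m]`.
#' The standard error of the flux is propagated from the slope standard
#' error.
#'
#' @param series A data frame with columns `time_h` and `conc_ppb` (one
#'   chamber deployment, >= 3 strictly increasing times). Columns `h_m`,
#'   `temp_c`, `pressure_kpa` and `chamber_id` override the corresponding
#'   arguments when present.
#' @param h Chamber height (headspace volume per area, m).
#' @param temp_c,pressure_kpa Conditions for the gas-law conversion.
#' @return A `flux_fit` object; see [glance.flux_fit()].
#' @examples
#' s <- sim_chamber_series(f0 = 50, kappa = 0)
#' glance(fit_linear_flux(s))
#' @seealso [fit_hm_flux()], [select_flux_model()]
#' @export
fit_linear_flux <- function(series, h = 0.2, temp_c = 10, pressure_kpa = 101.325) {
  env <- .series_env(series, h, temp_c, pressure_kpa)
  t <- env$t
  y <- env$y
  fit <- lm(y ~ t)
  slope <- coef(fit)[["t"]]
  se_slope <- .ols_slope_se(t, fit$residuals)
  conv <- ppb_to_ug_n_m3(env$temp_c, env$pressure_kpa)
  .new_flux_fit(
    f0 = slope * conv * env$h,
    se_f0 = se_slope * conv * env$h,
    model = "linear",
    kappa = NA_real_,
    phi = NA_real_,
    c0 = coef(fit)[["(Intercept)"]],
    sse = sum(fit$residuals^2),
    fitted = fit$fitted.values,
    env = env,
    converged = TRUE,
    k_par = 3
  )
}

#' Estimate chamber N2O flux by the Hutchinson-Mosier model
#'
#' Fits the exponential headspace model
#' \deqn{C(t) = \phi + (C_0 - \phi) e^{-\kappa t}}
#' by profiling the curvature rate \eqn{\kappa} over a log-spaced grid,
#' solving \eqn{(\phi, C_0)} by linear least squares at each candidate
#' (the model is linear in \eqn{\phi} and \eqn{\beta = C_0 - \phi} given
#' \eqn{\kappa}), then refining the best grid point by one-dimensional
#' optimization on the log scale. The pre-deployment flux is the initial
#' slope, \eqn{f_0 = h \kappa (\phi - C_0)}, converted to mass units.
#'
#' When the SSE profile has no interior minimum (e.g. exactly linear
#' data drive \eqn{\kappa} to the lower bound), the fit is flagged
#' non-converged (`selection_note = "no-HM-fit"`); callers such as
#' [select_flux_model()] then fall back to the linear fit.
#'
#' @inheritParams fit_linear_flux
#' @param kappa_bounds Positive bounds (h^-1) of the profiled curvature
#'   grid.
#' @param n_grid Number of log-spaced grid points.
#' @return A `flux_fit` object. The flux standard error is conditional on
#'   the fitted \eqn{\kappa} (it propagates the amplitude uncertainty
#'   only).
#' @examples
#' s <- sim_chamber_series(f0 = 100, kappa = 0.5, noise_sd = 0)
#' glance(fit_hm_flux(s))
#' @export
fit_hm_flux <- function(series, kappa_bounds = c(1e-3, 1e2), n_grid = 64,
                        h = 0.2, temp_c = 10, pressure_kpa = 101.325) {
  env <- .series_env(series, h, temp_c, pressure_kpa)
  if (length(env$t) < 4) {
    abort("HM fit needs at least 4 time points; use fit_linear_flux() instead.")
  }
  if (any(kappa_bounds <= 0) || kappa_bounds[1] >= kappa_bounds[2]) {
    abort("`kappa_bounds` must be positive and increasing.")
  }
  t <- env$t
  y <- env$y

  # SSE of the kappa-conditional linear fit C = phi + beta * exp(-kappa t)
  profile_sse <- function(kappa) {
    x <- exp(-kappa * t)
    f <- lm(y ~ x)
    sum(f$residuals^2)
  }
  lk <- seq(log(kappa_bounds[1]), log(kappa_bounds[2]), length.out = n_grid)
  sse <- vapply(lk, function(l) profile_sse(exp(l)), numeric(1))
  i <- which.min(sse)

  interior <- i > 1 && i < n_grid
  if (interior) {
    opt <- optimize(function(l) profile_sse(exp(l)),
      interval = c(lk[i - 1], lk[i + 1]), tol = 1e-10
    )
    kappa_hat <- exp(opt$minimum)
  } else {
    kappa_hat <- exp(lk[i])
  }

  x <- exp(-kappa_hat * t)
  f <- lm(y ~ x)
  phi <- coef(f)[["(Intercept)"]]
  beta <- coef(f)[["x"]] # C0 - phi
  conv <- ppb_to_ug_n_m3(env$temp_c, env$pressure_kpa)
  se_beta <- .ols_slope_se(x, f$residuals)
  .new_flux_fit(
    f0 = -env$h * kappa_hat * beta * conv,
    se_f0 = env$h * kappa_hat * se_beta * conv,
    model = "HM",
    kappa = kappa_hat,
    phi = phi,
    c0 = phi + beta,
    sse = sum(f$residuals^2),
    fitted = f$fitted.values,
    env = env,
    converged = interior,
    k_par = 4,
    selection_note = if (interior) "" else "no-HM-fit"
  )
}

#' Choose between the linear and Hutchinson-Mosier flux fits
#'
#' Algorithmic stand-in for the manual scatter-plot choice of regression
#' model: the HM fit is used only if it converged with an interior
#' curvature rate and improves AIC over the linear fit by more than
#' `delta_aic`; otherwise the linear fit is returned. The decision and
#' the AIC values are recorded in `selection_note`. A per-deployment
#' override (keyed by `chamber_id`) forces either model regardless of
#' AIC, preserving the option of expert judgement.
#'
#' @inheritParams fit_hm_flux
#' @param overrides Optional named character vector or two-column data
#'   frame (`chamber_id`, `model`) mapping chamber ids to `"linear"` or
#'   `"HM"`.
#' @param delta_aic Minimum AIC improvement required to prefer HM.
#' @return A `flux_fit` object.
#' @examples
#' s <- sim_chamber_series(f0 = 100, kappa = 0.5, noise_sd = 0)
#' glance(select_flux_model(s))$model
#' @export
select_flux_model <- function(series, overrides = NULL, delta_aic = 2,
                              kappa_bounds = c(1e-3, 1e2), n_grid = 64,
                              h = 0.2, temp_c = 10, pressure_kpa = 101.325) {
  lin <- fit_linear_flux(series, h = h, temp_c = temp_c, pressure_kpa = pressure_kpa)
  forced <- .lookup_override(overrides, lin$chamber_id)
  hm <- if (length(lin$data$time_h) >= 4) {
    tryCatch(
      fit_hm_flux(series,
        kappa_bounds = kappa_bounds, n_grid = n_grid,
        h = h, temp_c = temp_c, pressure_kpa = pressure_kpa
      ),
      error = function(e) NULL
    )
  } else {
    NULL
  }

  if (!is.null(forced)) {
    out <- if (forced == "HM" && !is.null(hm)) hm else lin
    out$selection_note <- sprintf("override: %s", forced)
    return(out)
  }
  if (is.null(hm) || !hm$converged) {
    lin$selection_note <- "linear: HM fit unavailable or not converged"
    return(lin)
  }
  daic <- lin$aic - hm$aic
  if (daic > delta_aic) {
    hm$selection_note <- sprintf(
      "HM: dAIC=%.2f > %.1f, kappa=%.3g interior", daic, delta_aic, hm$kappa
    )
    hm
  } else {
    lin$selection_note <- sprintf("linear: dAIC=%.2f <= %.1f", daic, delta_aic)
    lin
  }
}

#' Fit fluxes for every chamber deployment in a table
#'
#' Applies [select_flux_model()] per `chamber_id` and row-binds the
#' one-row [glance.flux_fit()] summaries — the batch entry point for a
#' campaign's worth of deployments.
#'
#' @param series_table Long table of concentration series with a
#'   `chamber_id` column plus the columns required by
#'   [fit_linear_flux()].
#' @inheritParams select_flux_model
#' @return A tibble with one row per chamber: `chamber_id`, `model`,
#'   `f0`, `se_f0`, `kappa`, `phi`, `sse`, `aic`, `n`, `selection_note`.
#' @export
estimate_fluxes <- function(series_table, overrides = NULL, ...) {
  check_columns(series_table, c("chamber_id", "time_h", "conc_ppb"))
  series_table %>%
    dplyr::group_split(.data$chamber_id) %>%
    purrr::map_dfr(function(s) glance(select_flux_model(s, overrides = overrides, ...)))
}

# ---- internals -------------------------------------------------------------

# slope standard error of a simple OLS fit, from residuals (avoids the
# summary.lm "perfect fit" warning on noiseless series)
.ols_slope_se <- function(x, resid) {
  n <- length(x)
  sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
}

.series_env <- function(series, h, temp_c, pressure_kpa) {
  check_columns(series, c("time_h", "conc_ppb"), arg = "series")
  t <- series$time_h
  y <- series$conc_ppb
  if (length(t) < 3) abort("A flux fit needs at least 3 time points.")
  if (any(diff(t) <= 0)) abort("`time_h` must be strictly increasing.")
  if (any(!is.finite(y))) abort("`conc_ppb` must be finite.")
  if (sd(t) == 0) abort("Zero variance in sampling times.")
  grab <- function(col, fallback) {
    if (col %in% names(series)) series[[col]][1] else fallback
  }
  list(
    t = t, y = y,
    h = grab("h_m", h),
    temp_c = grab("temp_c", temp_c),
    pressure_kpa = grab("pressure_kpa", pressure_kpa),
    chamber_id = as.character(grab("chamber_id", "chamber_1")),
    data = series
  )
}

.new_flux_fit <- function(f0, se_f0, model, kappa, phi, c0, sse, fitted, env,
                          converged, k_par, selection_note = "") {
  n <- length(env$t)
  structure(
    list(
      f0 = unname(f0), se_f0 = unname(se_f0), model = model,
      kappa = unname(kappa), phi = unname(phi), c0 = unname(c0),
      sse = sse, n = n,
      aic = n * log(max(sse, .Machine$double.xmin) / n) + 2 * k_par,
      converged = converged,
      selection_note = selection_note,
      chamber_id = env$chamber_id,
      h = env$h, temp_c = env$temp_c, pressure_kpa = env$pressure_kpa,
      data = as_tibble(env$data[c("time_h", "conc_ppb")]),
      fitted = unname(fitted)
    ),
    class = "flux_fit"
  )
}

.lookup_override <- function(overrides, chamber_id) {
  if (is.null(overrides)) {
    return(NULL)
  }
  if (is.data.frame(overrides)) {
    check_columns(overrides, c("chamber_id", "model"), arg = "overrides")
    overrides <- setNames(overrides$model, overrides$chamber_id)
  }
  m <- overrides[[chamber_id]]
  if (is.null(m) || is.na(m)) {
    return(NULL)
  }
  if (!m %in% c("linear", "HM")) abort("Override models must be 'linear' or 'HM'.")
  m
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf(
    "<flux_fit> %s  model=%s  f0=%.3g +/- %.2g ug N2O-N m-2 h-1\n",
    x$chamber_id, x$model, x$f0, x$se_f0
  ))
  if (x$model == "HM") {
    cat(sprintf("  kappa=%.3g h-1  phi=%.4g ppb\n", x$kappa, x$phi))
  }
  if (nzchar(x$selection_note)) cat("  ", x$selection_note, "\n", sep = "")
  invisible(x)
}

#' Tidy the parameters of a chamber flux fit
#'
#' @param x A `flux_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` (flux
#'   only; curve parameters carry `NA` standard errors).
#' @export
tidy.flux_fit <- function(x, ...) {
  tibble(
    term = c("f0", "kappa", "phi", "c0"),
    estimate = c(x$f0, x$kappa, x$phi, x$c0),
    std.error = c(x$se_f0, NA_real_, NA_real_, NA_real_)
  )
}

#' One-row summary of a chamber flux fit
#'
#' @param x A `flux_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `chamber_id`, `model`, `f0`, `se_f0`,
#'   `kappa`, `phi`, `sse`, `aic`, `n`, `selection_note`.
#' @export
glance.flux_fit <- function(x, ...) {
  tibble(
    chamber_id = x$chamber_id, model = x$model,
    f0 = x$f0, se_f0 = x$se_f0, kappa = x$kappa, phi = x$phi,
    sse = x$sse, aic = x$aic, n = x$n, selection_note = x$selection_note
  )
}

#' Observations with fitted values and residuals for a flux fit
#'
#' @param x A `flux_fit` object.
#' @param ... Unused.
#' @return The deployment's `time_h`/`conc_ppb` tibble plus `.fitted` and
#'   `.resid`.
#' @export
augment.flux_fit <- function(x, ...) {
  mutate(x$data, .fitted = x$fitted, .resid = .data$conc_ppb - x$fitted)
}

#' Plot a chamber deployment and its fitted concentration model
#'
#' @param object A `flux_fit` object.
#' @param ... Unused.
#' @return A ggplot: observed mixing ratios and the fitted linear or HM
#'   curve over the deployment window.
#' @export
autoplot.flux_fit <- function(object, ...) {
  grid <- tibble(time_h = seq(min(object$data$time_h), max(object$data$time_h),
    length.out = 100
  ))
  grid$conc_ppb <- if (object$model == "HM") {
    object$phi + (object$c0 - object$phi) * exp(-object$kappa * grid$time_h)
  } else {
    conv <- ppb_to_ug_n_m3(object$temp_c, object$pressure_kpa)
    object$c0 + object$f0 / (object$h * conv) * grid$time_h
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$conc_ppb)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Time since deployment (h)", y = expression(N[2] * O ~ "(ppb)"),
      title = sprintf(
        "%s: %s fit, f0 = %.1f ug N m-2 h-1",
        object$chamber_id, object$model, object$f0
      )
    )
}
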