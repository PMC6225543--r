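test_that("linear flux matches the ideal-gas arithmetic oracle", {
  # exact line 400 + 50 t ppb, h = 0.2 m, 20 C, 101.325 kPa
  s <- tibble::tibble(time_h = seq(0, 2, 0.5), conc_ppb = 400 + 50 * seq(0, 2, 0.5))
  fit <- fit_linear_flux(s, h = 0.2, temp_c = 20)
  expect_equal(fit$f0, 50 * oracle_ppb_to_ug_n_m3(20) * 0.2, tolerance = 1e-10)
  expect_equal(fit$se_f0, 0, tolerance = 1e-8)

  # constant concentration: zero flux, se from residuals
  s0 <- tibble::tibble(time_h = 0:4 / 2, conc_ppb = rep(350, 5))
  fit0 <- fit_linear_flux(s0)
  expect_equal(fit0$f0, 0)
  expect_gte(fit0$se_f0, 0)

  # slope is invariant under a constant time shift
  shifted <- dplyr::mutate(s, time_h = time_h + 3)
  expect_equal(fit_linear_flux(shifted, h = 0.2, temp_c = 20)$f0, fit$f0)

  # f0 scales with chamber height for the same concentration series
  expect_equal(fit_linear_flux(s, h = 0.4, temp_c = 20)$f0, 2 * fit$f0)
})

test_that("flux fits reject degenerate series", {
  expect_error(fit_linear_flux(tibble::tibble(time_h = c(0, 1), conc_ppb = c(1, 2))),
    "at least 3"
  )
  expect_error(
    fit_linear_flux(tibble::tibble(time_h = c(0, 1, 0.5), conc_ppb = 1:3)),
    "increasing"
  )
  expect_error(
    fit_hm_flux(tibble::tibble(time_h = c(0, 1, 2), conc_ppb = 1:3)),
    "at least 4"
  )
  expect_error(
    fit_hm_flux(sim_chamber_series(100, 0.5), kappa_bounds = c(1, 0.1)),
    "kappa_bounds"
  )
})

test_that("HM fit inverts the forward simulation to optimizer tolerance", {
  s <- sim_chamber_series(f0 = 100, kappa = 0.5, c0 = 330, h = 0.2, noise_sd = 0)
  fit <- fit_hm_flux(s)
  expect_equal(fit$model, "HM")
  expect_true(fit$converged)
  expect_lt(abs(fit$kappa - 0.5) / 0.5, 1e-4)
  expect_lt(abs(fit$f0 - 100) / 100, 1e-4)

  # uptake: concentrations decreasing toward an asymptote imply f0 < 0
  down <- sim_chamber_series(f0 = -60, kappa = 0.8, noise_sd = 0)
  expect_lt(fit_hm_flux(down)$f0, 0)
})

test_that("HM fit agrees with an independent nonlinear least-squares fit", {
  skip_if_not_installed("minpack.lm")
  s <- sim_chamber_series(f0 = 120, kappa = 1.2, c0 = 325, noise_sd = 3, seed = 11)
  fit <- fit_hm_flux(s)
  nls_fit <- minpack.lm::nlsLM(
    conc_ppb ~ phi + (c0 - phi) * exp(-k * time_h),
    data = s, start = list(phi = max(s$conc_ppb) + 50, c0 = s$conc_ppb[1], k = 1)
  )
  cf <- coef(nls_fit)
  f0_nls <- 0.2 * cf[["k"]] * (cf[["phi"]] - cf[["c0"]]) * oracle_ppb_to_ug_n_m3(10)
  expect_equal(fit$kappa, cf[["k"]], tolerance = 1e-4)
  expect_equal(fit$f0, f0_nls, tolerance = 1e-4)
})

test_that("exactly linear input pins kappa at the lower bound and is flagged", {
  s <- sim_chamber_series(f0 = 60, kappa = 0, noise_sd = 0)
  fit <- fit_hm_flux(s)
  expect_false(fit$converged)
  expect_match(fit$selection_note, "no-HM-fit")
})

test_that("near-linear data give matching HM and linear fluxes", {
  s <- sim_chamber_series(f0 = 100, kappa = 0.005, noise_sd = 0)
  hm <- fit_hm_flux(s)
  lin <- fit_linear_flux(s)
  expect_lt(abs(hm$f0 - lin$f0) / abs(lin$f0), 0.01)
})

test_that("model selection follows the AIC rule with override escape hatch", {
  curved <- sim_chamber_series(f0 = 100, kappa = 0.5, noise_sd = 0)
  expect_equal(select_flux_model(curved)$model, "HM")

  straight <- sim_chamber_series(f0 = 100, kappa = 0, noise_sd = 0)
  expect_equal(select_flux_model(straight)$model, "linear")

  forced <- select_flux_model(curved, overrides = c(chamber_1 = "linear"))
  expect_equal(forced$model, "linear")
  expect_match(forced$selection_note, "override")
})

test_that("batch estimation returns one tidy row per chamber", {
  tab <- dplyr::bind_rows(
    sim_chamber_series(100, 0.5, chamber_id = "c1", noise_sd = 0),
    sim_chamber_series(20, 0, chamber_id = "c2", noise_sd = 0)
  )
  out <- estimate_fluxes(tab)
  expect_equal(nrow(out), 2)
  expect_setequal(out$chamber_id, c("c1", "c2"))
  expect_equal(out$model, c("HM", "linear"))
})

test_that("broom and plot methods expose the fit", {
  fit <- select_flux_model(sim_chamber_series(100, 0.5, noise_sd = 1, seed = 3))
  td <- tidy(fit)
  expect_setequal(td$term, c("f0", "kappa", "phi", "c0"))
  expect_equal(nrow(glance(fit)), 1)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$conc_ppb - aug$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
})
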