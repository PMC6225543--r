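test_that("trapezoid weights follow the closed form and sum to the span", {
  expect_equal(trapezoid_weights(c(0, 1, 3)), c(0.5, 1.5, 1.0))
  # equally spaced: interior weights = delta, ends = delta / 2
  expect_equal(trapezoid_weights(seq(0, 20, by = 5)), c(2.5, 5, 5, 5, 2.5))
  for (dates in list(c(0, 7), c(0, 3, 4, 10), sort(runif(12, 0, 60)))) {
    expect_equal(sum(trapezoid_weights(dates)), max(dates) - min(dates))
  }
  expect_error(trapezoid_weights(5), "2 dates")
  expect_error(trapezoid_weights(c(0, 2, 2, 5)), "ties|increasing")
})

test_that("cumulative emission integrates exactly for constant and linear series", {
  # 10 ug m^-2 h^-1 over 60 d -> 0.144 kg N ha^-1
  const <- tibble::tibble(date = c(0, 30, 60), flux = 10)
  expect_identical(cumulative_emission(const, "ug_n_m2_h"), 10 * 24 * 60 * 1e4 * 1e-9)
  expect_equal(cumulative_emission(const, "ug_n_m2_h"), 0.144)

  # linear ramp 0 -> f over T gives f T / 2 exactly
  ramp <- tibble::tibble(date = seq(0, 50, by = 10), flux = seq(0, 40, by = 8))
  expect_equal(
    cumulative_emission(ramp, "ug_n_m2_h"),
    40 * 50 / 2 * 24 * 1e4 * 1e-9,
    tolerance = 1e-15
  )

  # g N ha^-1 d^-1 unit tag
  expect_equal(cumulative_emission(tibble::tibble(date = c(0, 10), flux = 100), "g_n_ha_d"), 1)
  expect_error(cumulative_emission(const), "flux_unit")
})

test_that("irregular series match a fine-grid piecewise-linear integral", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      dates <- sort(sample(0:70, 9))
      flux <- rgamma(9, 2, scale = 15)
      s <- tibble::tibble(date = dates, flux = flux)
      got <- cumulative_emission(s, "ug_n_m2_h")
      want <- fine_grid_integral(dates, flux) * 24 * 1e4 * 1e-9
      expect_equal(got, want, tolerance = 1e-6)
    }
  })
})

test_that("cumulate_emissions integrates every plot independently", {
  camp <- sim_flux_campaign(3, dates = c(100, 110, 130), mean_flux = c(5, 40, 8), seed = 4)
  out <- cumulate_emissions(camp, "ug_n_m2_h")
  expect_equal(nrow(out), 3)
  one <- dplyr::filter(camp, plot_id == "plot_01")
  expect_equal(
    out$cum_kg_n_ha[out$plot_id == "plot_01"],
    cumulative_emission(one[, c("date", "flux")], "ug_n_m2_h")
  )
})

test_that("emission factors reproduce the background-corrected ratios", {
  expect_equal(round(emission_factor(0.80, 0.25, 32.3), 3), 0.017)
  expect_equal(round(emission_factor(0.91, 0.18, 32.2), 3), 0.023)
  expect_equal(round(yield_scaled_ef(0.80, 0.25, 88.8), 3), 0.006)
  expect_equal(round(yield_scaled_ef(0.27, 0.25, 138.6), 3), 0.000)
  # background compared with itself is exactly zero; negatives are kept
  expect_equal(emission_factor(0.25, 0.25, 32.3), 0)
  expect_lt(emission_factor(0.20, 0.25, 100), 0)
  # linear in the (corrected) cumulative emission
  expect_equal(emission_factor(2 * 0.8 - 0.25, 0.25, 10), 2 * emission_factor(0.8, 0.25, 10))
  expect_error(emission_factor(1, 0, 0), "positive")
  expect_error(yield_scaled_ef(1, 0, -3), "positive")
})

test_that("ef_table reproduces the bundled study's emission factors", {
  ef <- ef_table(rotation_n_budget())
  key <- paste(ef$treatment, ef$year)
  expect_equal(round(ef$ef_area[key == "O4+CC-N 2011"], 3), 0.017)
  expect_equal(round(ef$ef_area[key == "O4+CC+N 2012"], 3), 0.007)
  expect_equal(round(ef$ef_yield[key == "C4-CC+N 2011"], 3), 0.000)
  expect_true(is.na(ef$ef_area[key == "O4-CC-N 2011"]))
})

test_that("Benjamini-Yekutieli adjustment matches the hand step-up", {
  expect_equal(by_fdr(0.03), 0.03) # m = 1: c(1) = 1
  # hand calculation with c(3) = 11/6
  expect_equal(by_fdr(c(0.01, 0.02, 0.04)), c(0.055, 0.055, 11 / 150))
  expect_equal(by_fdr(rep(1, 4)), rep(1, 4))
  # order preserved, adjusted >= raw, monotone in the order statistics
  withr::with_seed(8, {
    p <- runif(20)
    adj <- by_fdr(p)
    expect_true(all(adj >= p))
    expect_true(!is.unsorted(adj[order(p)]))
  })
  expect_error(by_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
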