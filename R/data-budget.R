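#' Published N budget of a two-year catch-crop rotation trial
#'
#' Treatment-level summaries from a long-term Danish crop-rotation field
#' experiment comparing spring barley under conventional (C4) and organic
#' (O4) management with (+CC) or without (-CC) a catch crop and with
#' (+N) or without (-N) spring N fertilization: spring cumulative N2O
#' emissions, N inputs from catch-crop residues and fertilizer, and plant
#' N uptake at harvest, for 2011 and 2012. The unamended treatment
#' O4-CC-N (no external N input) serves as the background for emission
#' factors.
#'
#' @return A tibble with columns `treatment`, `year`, `cum_kg_n_ha`,
#'   `catch_crop_n`, `fertilizer_n`, `plant_n` (all N quantities in
#'   kg N ha^-1; `plant_n` is `NA` where not determined).
#' @examples
#' rotation_n_budget()
#' @seealso [ef_table()]
#' @export
rotation_n_budget <- function() {
  path <- system.file("extdata", "rotation_n_budget.csv",
    package = "denitflux", mustWork = TRUE
  )
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Background-corrected emission factors for a treatment table
#'
#' Computes area-based and yield-scaled N2O emission factors for every
#' (treatment, year) of an N budget table, subtracting the cumulative
#' emission of the background treatment within the same year. The N input
#' is catch-crop N plus fertilizer N; the background treatment itself
#' gets `NA` factors (it has no external input).
#'
#' @param budget A data frame shaped like [rotation_n_budget()].
#' @param background_treatment Treatment whose emission is the
#'   within-year background.
#' @return The input plus `n_input`, `ef_area` (fraction) and `ef_yield`
#'   (kg N2O-N per kg plant-N).
#' @examples
#' ef_table(rotation_n_budget())
#' @export
ef_table <- function(budget, background_treatment = "O4-CC-N") {
  check_columns(budget, c(
    "treatment", "year", "cum_kg_n_ha", "catch_crop_n", "fertilizer_n", "plant_n"
  ))
  if (!background_treatment %in% budget$treatment) {
    abort(sprintf("Background treatment '%s' not found.", background_treatment))
  }
  budget %>%
    group_by(.data$year) %>%
    mutate(
      background = .data$cum_kg_n_ha[.data$treatment == background_treatment][1],
      n_input = .data$catch_crop_n + .data$fertilizer_n,
      ef_area = ifelse(
        .data$n_input > 0,
        emission_factor(.data$cum_kg_n_ha, .data$background, pmax(.data$n_input, 1e-12)),
        NA_real_
      ),
      ef_yield = ifelse(
        is.na(.data$plant_n), NA_real_,
        yield_scaled_ef(
          .data$cum_kg_n_ha, .data$background,
          ifelse(is.na(.data$plant_n), 1, .data$plant_n)
        )
      )
    ) %>%
    ungroup()
}
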