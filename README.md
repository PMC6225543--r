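# denitflux

Quantifying nitrous oxide emissions from arable soil — and the
denitrifier communities behind them — involves a chain of small but
error-prone computations that are usually scattered across spreadsheets
and one-off scripts. `denitflux` packages that chain for chamber-based
N₂O field studies with T-RFLP community fingerprinting:

* **Chamber flux estimation.** The headspace of a closed static chamber
  follows the Hutchinson–Mosier model
  C(t) = φ + (C₀ − φ)e^(−κt), whose initial slope gives the
  pre-deployment surface flux f₀ = hκ(φ − C₀) (converted from ppb to
  µg N₂O-N m⁻² h⁻¹ by the ideal gas law). `fit_hm_flux()` profiles κ
  over a log-spaced grid with the curve parameters solved by linear
  least squares at each candidate; `select_flux_model()` arbitrates
  between the nonlinear and linear fits with an AIC rule and a
  per-chamber override.
* **Cumulative emissions and emission factors.** `trapezoid_weights()`
  builds the weight vector w with Σwᵢfᵢ equal to the trapezoidal
  integral of a flux series (the same coefficients serve as GLMM
  contrast weights); `emission_factor()` and `yield_scaled_ef()` compute
  background-corrected EF = (cum − background)/N. `by_fdr()` applies the
  Benjamini–Yekutieli step-up for multiple comparisons.
* **Soil aeration.** `wfps()` and `relative_gas_diffusivity()` implement
  water-filled pore space and the structure-dependent
  Dp/D₀ = Φ²(ε/Φ)^X model with X = 2 + log(ε₁₀₀^0.25)/log(ε₁₀₀/Φ).
* **T-RFLP alignment.** A complete peak-table processing algorithm:
  closest-pair merging of shoulder peaks, within-profile relativization,
  iterative 3σ baseline noise classification, pairwise dynamic-programming
  alignment of size-sorted peak lists, random-order incremental multiple
  alignment with consensus averaging, and leave-one-out refinement that
  accepts a pass only if the overall alignment score improves.
  `wisconsin_standardize()` and `bray_curtis()` prepare the resulting
  sample × bin matrices for ordination.
* **Synthetic data with ground truth.** `sim_chamber_series()`,
  `sim_flux_campaign()` and `sim_trflp_profiles()` generate every input
  with known truth labels, so flux recovery, integration accuracy and
  bin recovery can be scored exactly.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()`/`augment()` methods,
and `autoplot()` draws fitted chamber curves and false-gel images.

## Worked example

Fit one noisy simulated chamber deployment (true f₀ = 100 µg N₂O-N
m⁻² h⁻¹, κ = 0.5 h⁻¹, 5 ppb sampling noise):

```r
library(denitflux)
s <- sim_chamber_series(f0 = 100, kappa = 0.5, noise_sd = 5, seed = 42)
glance(select_flux_model(s))
#>   chamber_id model    f0 se_f0 kappa   phi   sse   aic     n selection_note
#> 1 chamber_1  HM     96.6 0.692 0.464 1200.  26.4  16.3     5 HM: dAIC=21.98 > 2.0, ...
```

The HM model is selected and recovers the true flux within a few
percent. Emission factors from the bundled two-year rotation trial
budget (organic rotation with catch crop, no fertilizer):

```r
ef_table(rotation_n_budget()) |>
  dplyr::filter(treatment == "O4+CC-N") |>
  dplyr::select(treatment, year, cum_kg_n_ha, n_input, ef_area, ef_yield)
#>   treatment  year cum_kg_n_ha n_input ef_area ef_yield
#> 1 O4+CC-N    2011        0.8     32.3  0.0170  0.00619
#> 2 O4+CC-N    2012        0.91    32.2  0.0227  0.00851
```

i.e. 1.7% and 2.3% of the catch-crop residue N was emitted as N₂O-N.
End-to-end fingerprint recovery on synthetic profiles (20 samples,
15 true fragments, 0.2 bp size-calling jitter, ~30 spurious peaks per
profile, shoulder peaks on):

```r
peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 20, seed = 7)
res   <- align_trflp(peaks, seed = 7)
aln   <- res$alignments[["nirK_HaeIII"]]
glance(aln)
#>   gene  enzyme n_samples n_bins score n_refine_passes
#> 1 nirK  HaeIII        20     15  58.3               0
bin_purity(aln)                    # 1  (every true peak co-binned with its cohort)
noise_discard_rate(res$classified) # 1  (every spurious peak removed)
```

All 15 true fragments come back as exactly 15 bins with full occupancy;
`autoplot(aln)` draws the false-gel image for visual inspection.

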