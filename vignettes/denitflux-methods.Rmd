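---
title: "Methods: chamber N2O fluxes, emission factors, and T-RFLP alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber N2O fluxes, emission factors, and T-RFLP alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitflux)
```

`denitflux` implements the computational chain of a chamber-based N₂O
field study with denitrifier community fingerprinting. This vignette
documents the models, their assumptions, the tunable parameters, and
the design decisions taken where the underlying methods left choices
open.

## Chamber flux estimation

A vented static chamber of height $h$ (headspace volume per covered
soil area, m) accumulates N₂O according to the Hutchinson–Mosier (HM)
model

$$C(t) = \phi + (C_0 - \phi)\,e^{-\kappa t},$$

where $C_0$ is the mixing ratio at deployment (ppb), $\phi$ the
asymptote the headspace approaches as the soil–chamber gradient
collapses, and $\kappa \ge 0$ (h⁻¹) the curvature rate. The surface
flux before deployment is the initial slope,
$f_0 = h\,\kappa\,(\phi - C_0)$, converted from mixing ratio to mass by
the ideal gas law at the deployment's air temperature and pressure
(28 g N per mol N₂O; pressure defaults to 101.325 kPa because chamber
campaigns rarely log barometric pressure). As $\kappa \to 0$ the model
degenerates to the linear accumulation $C(t) = C_0 + (f_0/h\,c)t$ (with
$c$ the ppb-to-mass factor), which is the appropriate model when
diffusion feedback is negligible.

`fit_hm_flux()` exploits that the model is linear in $(\phi, C_0)$
given $\kappa$: it profiles the residual sum of squares over 64
log-spaced $\kappa$ values on $[10^{-3}, 10^{2}]$ h⁻¹, solving the
conditional linear least-squares problem at each, then refines the best
grid point by one-dimensional optimization on the log scale
(tolerance $10^{-10}$). This one-dimensional profiling is robust where
a free three-parameter exponential fit on five points routinely
diverges. If the SSE profile attains its minimum at a grid boundary
(exactly linear data push $\kappa$ to the lower bound), the fit is
flagged `no-HM-fit` and callers fall back to the linear estimator. The
reported `se_f0` propagates the conditional amplitude uncertainty at
the fitted $\kappa$; it does not include $\kappa$ uncertainty, which
would require the full curvature of the profile likelihood.

Field practice chooses between the linear and nonlinear fits by eye.
For reproducibility `select_flux_model()` replaces that judgement by an
explicit rule — the HM fit is used only if it converged with an
interior $\kappa$ and improves AIC by more than 2 (AIC computed from
Gaussian residuals, penalizing the extra curvature parameter) — while a
per-chamber override table preserves the option of expert choice.

Default geometry (0.20 m chamber height, five samples over two hours)
mirrors a typical deployment. With 5 ppb sampling noise on a
100 µg N₂O-N m⁻² h⁻¹ flux, the median relative flux error over 500
simulated deployments stays well below 10% (the test suite measures
this directly).

## Cumulative emissions and emission factors

The integral of a flux series observed at dates $t_1 < \dots < t_n$ is
approximated trapezoidally, which for point observations equals
$\sum_i w_i f_i$ with end weights $(t_2-t_1)/2$, $(t_n-t_{n-1})/2$ and
interior weights $(t_{i+1}-t_{i-1})/2$. `trapezoid_weights()` exposes
this weight vector separately because the same coefficients serve as
contrast weights when cumulative emissions are estimated inside a gamma
GLMM of the per-date fluxes: the mixed-model route is deliberately left
to `lme4` (the weights are what this package contributes), while
`cumulative_emission()` applies them directly to plot-level series.
Unit handling is explicit — a flux series must carry one of the two
supported unit tags (`ug_n_m2_h` or `g_n_ha_d`); nothing is guessed.

Area-based emission factors are background-corrected fractions
$\mathrm{EF} = (\mathrm{cum} - \mathrm{background})/N_\mathrm{input}$,
with the unamended treatment serving as background and
$N_\mathrm{input}$ the catch-crop residue N plus fertilizer N where
both apply. Yield-scaled factors divide by the N in harvested biomass
instead. Negative factors are reported, not truncated: a treatment can
emit less than the background. Note that yield-scaled factors computed
this way from the bundled 2012 budget rows do not reproduce every
published 2012 value — plant-uptake data other than the bundled table
appear to underlie those — so the package documents and tests only the
internally consistent entries.

P-values from the many pairwise treatment contrasts are adjusted by the
Benjamini–Yekutieli step-up (`by_fdr()`, delegating to
`stats::p.adjust(method = "BY")`), which controls the FDR under the
arbitrary dependence created by shared contrast weights.

## Soil aeration metrics

With gravimetric water $\theta_g$ and dry bulk density $\rho_b$
(particle density $\rho_s = 2.65$ g cm⁻³ by default, the standard
mineral-soil value for a sandy loam), total porosity is
$\Phi = 1 - \rho_b/\rho_s$, volumetric water
$\theta_v = \theta_g \rho_b$, and WFPS $= \theta_v/\Phi$, so that
WFPS $+ \varepsilon/\Phi = 1$ exactly. Relative gas diffusivity uses
the structure-dependent model

$$D_p/D_0 = \Phi^2 (\varepsilon/\Phi)^{X}, \qquad
X = 2 + \frac{\log(\varepsilon_{100}^{0.25})}{\log(\varepsilon_{100}/\Phi)},$$

with $\varepsilon_{100}$ the air content at −100 cm H₂O, a user input
(no water-retention fitting is attempted). The log base cancels in the
ratio; $\varepsilon_{100} = \Phi$ makes the exponent undefined and is
rejected with an explanatory error. The model is monotone in
$\varepsilon$ and bounded by $\Phi^2$, both asserted in tests.

Growing-degree-day sums clamp at a base temperature,
$\sum_d \max(0, T_d - T_\mathrm{base})$. Published GDD conventions for
spring cereals differ in $T_\mathrm{base}$; this package defaults to
0 °C and flags the choice as an assumption via the `t_base` argument.

## The T-RFLP alignment algorithm

Input is a Peak Scanner-style long table of detected terminal
restriction fragments (sample, gene, restriction enzyme, fragment size
in bp — fractional, from size calling against an internal standard —
area, height). Sizes are treated as continuous throughout; no integer
rounding is applied. Processing proceeds in five stages.

**1. Shoulder merging** (`smooth_peaks()`). Sizing software frequently
splits one fragment into a main peak and a "shoulder" a fraction of a
bp away. Within each profile, the closest pair of peaks separated by
less than the merge window δ (default 0.5 bp) is merged — area-weighted
mean size, summed area, maximum height — and the scan repeats until no
pair remains. Closest-pair-first matters: the rule is deterministic
(leftmost pair on exact ties) and the tests pin its cascading behaviour
on a hand-worked chain. Merging operates on the peak table; a
kernel-density smoother over raw electropherogram traces would need the
traces themselves, which sit upstream of this package's inputs.

**2. Relativization** (`relativize_peaks()`). Areas and heights are
each divided by their within-profile totals, making profiles comparable
across samples with different PCR yields and injection amounts.

**3. Noise classification** (`classify_peaks()`). Following the
iterative baseline idea used for fingerprint de-noising, all peaks of
one (gene, enzyme) across all samples are pooled; the standard
deviation of relative areas about a theoretical baseline of zero,
$\sigma_a = \sqrt{\sum a_i^2 / n}$ (and $\sigma_h$ likewise), is
computed over peaks not yet flagged; every peak exceeding
$k\sigma$ (default $k = 3$) is flagged as signal and removed from the
pool, and the procedure iterates until fixpoint. Whether a signal peak
must exceed the threshold in *both* area and height or in *either* is
ambiguous in common descriptions; the default here is the conservative
AND rule, switchable via `align_params(noise_rule = "or")`. Two
behaviours are worth knowing: a pool of identical peaks can never
exceed three times its own RMS, so degenerate profiles classify as all
noise; and the cascade relies on the pool containing many genuinely
small peaks — in data with very few noise peaks and a compressed
abundance range, the baseline is dominated by signal and the classifier
is deliberately conservative.

**4. Multiple alignment** (`align_profiles()`). Pairwise alignment of
two size-sorted peak lists is a global dynamic program
(Needleman–Wunsch over the two sequences): matching peaks $p, q$ costs
$d(p,q) = w_s|\Delta \mathrm{size}| + w_a|\Delta \mathrm{area}| +
w_h|\Delta \mathrm{height}|$, matches are infeasible beyond a maximum
size drift $D_{\max}$ (default 1.0 bp), and every unmatched peak costs the
gap penalty $g$ (default 0.75). With relative signals in $[0,1]$ and
sizes in bp, unit weights put the three components on comparable
scales, and a match beats two gaps whenever $d < 2g = 1.5$. Ties prefer
a match over a gap, deterministically. The DP is provably optimal over
monotone (non-crossing) matchings; the tests verify it against
exhaustive enumeration on hundreds of toy instances.

The multiple alignment starts from a random pair of profiles (seeded)
and adds the remaining profiles in random order, each aligned against
the running consensus — bins summarized by the unweighted mean size,
area, and height of their current members. Matched peaks join their
bin; unmatched peaks open new singleton bins. The overall score is the
sum over member peaks of the dissimilarity to their bin consensus plus
$g$ for every (bin, sample) slot with no peak — the gap term gives the
score an incentive to merge compatible fragment bins rather than
fragment them, mirroring the pairwise objective.

**5. Refinement** (`refine_alignment()`). Incremental alignment is
order-dependent, so a leave-one-out pass removes each sample in seeded
random order (bin averages recomputed without it, empty bins dropped)
and realigns it to the remaining consensus. A full pass is kept only if
the overall score strictly decreased; otherwise the previous alignment
is restored and refinement terminates (hard cap
`max_refine_iters = 20`). The accepted score sequence is strictly
decreasing by construction, and the stored score always equals the
score recomputed from the membership (`alignment_score()`).

Per-gene tables from the two restriction digests are concatenated
column-wise with enzyme-prefixed bin ids (`combine_enzymes()`), and
genes are combined the same way (`combine_genes()`). For ordination,
`wisconsin_standardize()` (column maxima, then row totals — delegated
to vegan with added input validation) and `bray_curtis()`
($\sum|x-y| / \sum(x+y)$; a semimetric — the triangle inequality is not
guaranteed and not asserted) produce the matrices that `vegan::metaMDS`
and `envfit` consume; the ordination itself is deliberately out of
scope.

Manual correction of automated binning is supported only insofar as the
membership table is an ordinary tibble the user can edit and re-score;
no interactive tooling is provided.

## Synthetic-data generators

The generators exist so that every stage can be scored against known
truth without any field data; they emulate the *structure* of real
inputs, not any particular dataset.

* `sim_chamber_series()` draws concentrations from the exact HM curve
  (or its linear limit) plus i.i.d. Gaussian noise. Defaults: 0.20 m
  chamber, five samples over 2 h, 10 °C. Noise-free series are exactly
  invertible by the fitters — the basis of the parameter-recovery
  tests.
* `sim_flux_campaign()` draws per-plot, per-date fluxes from a gamma
  distribution parameterized by (mean, shape), matching the skewed,
  strictly positive character of field N₂O fluxes; `pulse_mean_flux()`
  supplies a fertilization-pulse mean trajectory (background ~3, peak
  ~80 µg N₂O-N m⁻² h⁻¹ a few days after fertilization, e-folding decay
  of 10 days) of the kind spring campaigns show.
* `sim_trflp_profiles()` emits labelled peak tables: 15 true fragments
  evenly spaced over 60–480 bp whose mean relative abundances follow a
  geometric series spanning one order of magnitude — community
  fingerprints are dominated by a few abundant fragments, and the
  iterative 3σ classifier requires exactly this spread to cascade from
  the dominant peaks downwards (a feasibility check done analytically
  before the defaults were frozen). Per-sample size-calling jitter is
  Gaussian (0.2 bp), areas log-normal (sdlog 0.3) with correlated
  heights, shoulders appear +0.3 bp from their parent with 5–25% of its
  area, and Poisson(30) spurious peaks carry areas below 10% of the
  profile's smallest true peak. True fragment sizes must be separated
  by more than 3× the jitter SD so that cohort recovery is well
  defined.

What the generators do **not** emulate: pink/correlated detector noise,
size-dependent calling bias, partial digestion, PCR chimeras, true
fragments absent from some samples, and plot-level spatial correlation
of fluxes. Passing tests therefore demonstrate algorithmic correctness
under a clean error model, not robustness to every field artifact.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with informative errors
(non-increasing times, all-zero profiles, background porosity
violations, missing unit tags). Ties in the merge step break leftmost;
ties in the DP prefer matches. The refinement acceptance test uses a
$10^{-12}$ slack so floating-point no-ops cannot masquerade as
improvements.

The test suite and acceptance script run entirely on synthetic or
bundled tabular inputs at desk scale: 500 chamber deployments for the
noise-recovery property, 200 toy instances for the DP-vs-enumeration
equivalence, and a 20-sample × 15-fragment fingerprint for end-to-end
bin recovery — sizes chosen to exercise every code path in seconds
while matching the scale of a real two-year campaign (two years × five
treatments × replicate chambers).
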