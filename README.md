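# lignoporo

Analysis pipelines for the physico-chemical characterization of
lignocellulosic biomass — wood whose cell walls have been engineered
(for example by ectopic callose deposition) and whose changed water
behaviour, porosity and composition need quantifying. The package is
aimed at plant cell-wall and biomass researchers who have instrument
exports (DVS mass/time traces, DSC heat-flow thermograms, fluorescence
z-stacks, grouped scalar measurements) and want a scripted, testable
version of the usual desk analyses.

Four pipelines, each paired with a ground-truth simulator:

- **DVS sorption** (`detect_equilibria`, `build_isotherm`, `fit_park`,
  `mrd`, `hysteresis`): kinetic traces → equilibrium mass gain
  `M = (m_eq − m_d)/m_d × 100` per water-activity step → five-parameter
  Park isotherm
  `M(a_w) = A_L b_L a_w/(1 + b_L a_w) + k_H a_w + n k_H^n k_a a_w^n`
  fitted by multi-start nonlinear least squares, with the mean relative
  percentage deviation modulus
  `MRD = (100/N) Σ |m_i − m_pi| / m_i` (below 10 % = good fit).
- **DSC thermoporosimetry** (`segment_steps`, `integrate_endotherm`,
  `pore_distribution`, `thermogram_to_pores`): stepwise-isothermal
  melting thermograms → Gibbs–Thomson pore diameters
  `D = 4 T₀ γ cosθ / ((T_m − T₀) ρ H_f)`
  (defaults T₀ = 273.15 K, γ = 12.1 mJ m⁻², θ = 180°, ρ = 1000 kg m⁻³,
  H_f = 334 J g⁻¹) → freezing-water fractions per diameter bin plus bulk
  free water.
- **Immunofluorescence quantification** (`max_project`, `wall_mask`,
  `mean_fluorescence`, `relative_intensity`): z-stack maximum projection,
  counterstain-thresholded wall mask (manual or Otsu, optional ROI
  polygon), masked mean intensity of the immunolabel channel, and
  between-line fold changes with section-level bootstrap CIs.
- **Group statistics** (`assumption_gate`, `compare_groups`,
  `letter_groups`, `type1_error_sim`): Shapiro + Bartlett gate at
  α = 0.05, then one-way ANOVA + Tukey HSD or Kruskal–Wallis +
  Tukey-type all-pairs rank comparisons, summarized as a compact letter
  display whose consistency is verified on every call. Plus
  `green_density` and `percent_change` calculators.

The synthetic module (`gen_park_isotherm`, `gen_dvs_kinetics`,
`gen_dsc_thermogram`, `gen_image_stack`, `gen_grouped_measurements`) is
first-class, seeded and deterministic; every analysis is validated by
forward–inverse round trips against it.

## Worked example

```r
library(lignoporo)

# --- Park fit on a simulated 9-point isotherm with 1% relative noise
truth <- park_params(A_L = 1, b_L = 10, k_H = 5, k_a = 0.5, n = 4)
iso <- gen_park_isotherm(truth, seq(0.1, 0.9, 0.1), noise_sd = 0.01, seed = 42)
fit_park(iso)
#> Park model fit (9 points)
#> Park model parameters:
#>   A_L = 0.3573  b_L = 3.451e+07  k_H = 6.609  k_a = 0.1602  n = 4.016
#>   MRD = 0.464%  (below 10% indicates a good fit)
#>   weighted SSE = 0.0003125  converged: TRUE

# --- thermoporosimetry round trip on a 4-32 nm mesopore distribution
edges <- exp(seq(log(4e-9), log(32e-9), length.out = 6))
prog <- step_program(temp_C = c(-30,
  melting_temperature_for_diameter(edges) - 273.15, 2), duration_s = 600)
dist <- pore_size_distribution(
  data.frame(d_low_m = edges[-6], d_high_m = edges[-1],
             water_fraction_pct = c(10, 15, 20, 25, 10)),
  free_water_fraction_pct = 20, total_freezing_water_mg = 4)
tg <- gen_dsc_thermogram(dist, prog, seed = 1)
thermogram_to_pores(tg, prog)
#> Pore-size distribution (freezing water)
#>     4.00 -   6.06 nm :  10.0 %
#>     6.06 -   9.19 nm :  15.0 %
#>     9.19 -  13.93 nm :  20.0 %
#>    13.93 -  21.11 nm :  25.0 %
#>    21.11 -  32.00 nm :  10.0 %
#>   free (bulk) water  :  20.0 %
#>   total freezing water: 4.000 mg
# (leading empty bins below 4 nm omitted here for brevity)

# --- assumption-gated comparison with compact letters
d <- gen_grouped_measurements(list(
  list(label = "WT",    dist = "normal", mean = 10, sd = 1, n = 10),
  list(label = "lineA", dist = "normal", mean = 12, sd = 1, n = 10),
  list(label = "lineB", dist = "normal", mean = 15, sd = 1, n = 10)),
  seed = 2)
compare_groups(d)
#> One-way comparison (parametric path), omnibus p = 2.846e-09
#> Letters (alpha = 0.05 ):
#> lineA lineB    WT
#>   "a"   "b"   "c"
```

The MRD of 0.46 % says the fitted curve deviates from the noisy
observations by under half a percent on average — a good fit by the usual
10 % criterion. Note how the individual Park parameters trade off against
each other at this noise level (the huge `b_L` simply saturates the
Langmuir term into a constant offset); at zero noise all five are
recovered to within 5 %, see the test suite. The pore table is the Fig.-3b-style histogram: each row
is the share of freezing water held in pores of that diameter range. The
letter display reads as usual: groups sharing no letter differ at
p < 0.05.

A command-line front end mirrors the library
(`inst/cli/lignoporo.R`): `simulate`, `dvs-fit`, `dsc-pores`,
`quantify-image`, `compare-groups`, `metrics`.

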