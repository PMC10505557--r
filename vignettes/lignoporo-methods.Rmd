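---
title: "Methods: sorption isotherms, thermoporosimetry, fluorescence quantification and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoporo)
```

`lignoporo` implements the physico-chemical readouts used to characterize
modified lignocellulosic biomass — for instance wood in which an extra
polysaccharide such as callose has been deposited into the secondary cell
wall. Four instrument pipelines are covered: dynamic vapour sorption
(DVS), DSC thermoporosimetry, immunofluorescence quantification and the
group-comparison statistics applied to all scalar readouts. Every pipeline
has a matching simulator with known ground truth, so the whole package is
testable end to end without instrument data.

## Water vapour sorption and the Park model

A DVS instrument records sample mass against time while the water activity
$a_w$ (relative humidity / 100) is stepped through a program, classically
$0 \rightarrow 0.1 \rightarrow \dots \rightarrow 0.9 \rightarrow \dots
\rightarrow 0$. The mass gain at equilibrium for each step is

$$M = \frac{m_{eq} - m_d}{m_d} \times 100,$$

in percent of the dry mass $m_d$ (mass after dry-nitrogen equilibration).
Equilibrium is declared when the drift $|dm/dt|$, measured as the OLS slope
over a trailing window, falls below a threshold. Published protocols
usually call the threshold "predefined" without stating it; our defaults
are **0.002 % of dry mass per minute over a 10-minute window**, both
configurable. A hold that
never meets the criterion keeps its terminal mass but is flagged
`equilibrated = FALSE` rather than silently accepted.

Equilibrium points form the sorption and desorption isotherms, which are
fitted with the five-parameter Park model,

$$M(a_w) = \frac{A_L b_L a_w}{1 + b_L a_w} + k_H a_w
  + n\,k_H^n k_a a_w^n,$$

i.e. Langmuir adsorption on specific sites ($A_L$, capacity, %; $b_L$,
affinity), Henry-law dissolution ($k_H$, % per unit $a_w$) and water
clustering at high activity ($k_a$, clustering equilibrium constant; $n$,
mean cluster size). Fitting is relative ($1/M^2$-weighted) nonlinear
least squares
(Levenberg–Marquardt, `minpack.lm`), multi-started from a
$3\times3\times3$ lattice of $(b_L, k_a, n)$ initial values with $A_L$ and
$k_H$ seeded from the data; all parameters are bounded at zero and $n \ge
1$ is treated as continuous (nothing constrains clusters to integer
sizes). Goodness of fit is reported as the mean relative percentage
deviation modulus,

$$\mathrm{MRD} = \frac{100}{N}\sum_{i=1}^{N}
  \frac{|m_i - m_{p i}|}{m_i}.$$

Relative weighting is the maximum-likelihood objective when the balance
error scales with the signal (sorption accuracy is quoted in percent),
and it matters here: the clustering term can make the mass gain at
$a_w = 0.9$ several hundred times the $a_w = 0.1$ value, and an
unweighted fit then spends its five parameters chasing noise on the
large points while the small points — which dominate the
relative-deviation diagnostic — drift by tens of percent. MRD carries
the conventional reading that a value below 10 % indicates a good fit;
it is a diagnostic, never the optimization target, and observed values of
exactly zero are excluded (with a warning) because the relative deviation
is undefined there.

```{r park}
truth <- park_params(A_L = 1, b_L = 10, k_H = 5, k_a = 0.5, n = 4)
iso <- gen_park_isotherm(truth, seq(0.1, 0.9, 0.1), noise_sd = 0.01, seed = 42)
fit_park(iso)
```

The kinetic simulator relaxes the mass exponentially toward each step's
Park equilibrium, $m(t) = m_{eq} - (m_{eq} - m_{start})e^{-t/\tau}$ —
the simplest law satisfying the equilibrium criterion; real DVS kinetics
are diffusion-limited and more structured, so passing round trips say
nothing about diffusivity. Default $\tau$ = 600 s and holds of 8$\tau$
(4800 s), so the residual relaxation $e^{-8} \approx 3\times10^{-4}$ is
negligible against the equilibrium threshold; deliberately truncated holds
(2$\tau$) are the test bed for the not-equilibrated flag. The branch split
assigns every hold up to (and tied with) the maximum activity to sorption,
the rest to desorption. Because the simulator is history-free, any
apparent hysteresis in a round trip bounds the pipeline's numerical error
— observed below 0.005 % mass gain at zero noise — whereas real wood shows
genuine sorption hysteresis.

## DSC thermoporosimetry

Water confined in pores melts below the bulk melting point; approximating
pores as cylinders, the Gibbs–Thomson relation gives the pore diameter

$$D = \frac{4\,T_0\,\gamma \cos\theta}{(T_m - T_0)\,\rho\,H_f},$$

with defaults $T_0 = 273.15$ K, $\gamma = 12.1$ mJ m$^{-2}$, $\theta =
180^\circ$, $\rho = 1000$ kg m$^{-3}$, $H_f = 334$ J g$^{-1}$ (the
conventional constants for water in lignocellulosic substrates). A 1 K
depression maps to 39.6 nm and $D \propto 1/\Delta T$, so depressions of
roughly 1.2–10 K span the 4–32 nm mesopore window of interest. Internally
everything is SI ($\gamma \to$ J m$^{-2}$, $H_f \to$ J kg$^{-1}$);
temperatures are accepted in °C at the file interface.

The experiment melts the frozen, water-saturated sample through a series
of isothermal holds. The analysis (i) segments the thermogram into hold
windows — for each programmed temperature the longest contiguous run
within ±0.05 K; (ii) integrates the endotherm in each window above a
baseline (endpoint-anchored linear by default, flat for drift-free
traces; small negative areas are clipped to zero with a warning as noise
artifacts); (iii) converts each specific enthalpy to melting water mass
via $m = \Delta H \cdot m_{sample} / H_f$ and assigns it to the diameter
interval between the previous and the current hold temperature:
**water melting during the hold at $T_k$ occupies pores with
$D \in (D(T_{k-1}), D(T_k)]$**, the first bin's lower edge coming from the
starting (coldest) temperature. We state this edge rule explicitly because
"a calculated diameter range" admits both conventions; the chosen one is
the physically consistent reading ($D$ increases with $T_m$). Holds within
0.2 K of $T_0$ — where the relation diverges (D > ~200 nm) — are pooled as
bulk free water. Fractions are normalized to **total freezing water**
(confined + free = 100 %); normalization to total water including
non-freezing bound water would need the oven-dry reference from
`total_water_content()` and is left to the user.

The default hold schedule (−30, −10, −5, −3, −2, −1.2, −0.6, −0.2, +2 °C,
600 s each) is a configurable package choice: published schedules for this
experiment typically live in supplementary material and vary between
laboratories, so every schedule-dependent result is
configuration-relative. The simulator writes one Gaussian endotherm per
hold, centred mid-hold with $\sigma$ = 20 s (areas are all that matter to
the analysis; the shape is free), ramps at 0.05 K s$^{-1}$ between holds,
and declares the endotherm-positive ("exo down") sign convention in the
metadata. Round trips at zero noise recover 5-bin mesopore distributions
to well under 1 percentage point and conserve total water mass to better
than 0.5 %; supercooling, ice nucleation kinetics and non-cylindrical
geometry corrections are deliberately out of scope.

```{r dsc}
edges <- exp(seq(log(4e-9), log(32e-9), length.out = 6))
prog <- step_program(temp_C = c(-30, melting_temperature_for_diameter(edges)
                                - 273.15, 2), duration_s = 600)
dist <- pore_size_distribution(
  data.frame(d_low_m = edges[-6], d_high_m = edges[-1],
             water_fraction_pct = c(10, 15, 20, 25, 10)),
  free_water_fraction_pct = 20, total_freezing_water_mg = 4)
tg <- gen_dsc_thermogram(dist, prog, seed = 1)
suppressWarnings(thermogram_to_pores(tg, prog))
```

## Immunofluorescence quantification

The imaging workflow reproduces the standard macro for quantifying an
immunolabel restricted to the cell wall: maximum projection of the
z-stack, a binary mask from the cell-wall counterstain channel
(calcofluor-style), and the mean of the immunolabel channel over the
masked pixels — masking first, so lumina do not dilute the wall signal.
The interactive original uses a hand-drawn region of interest and a
user-chosen threshold; both are supported (ROI polygons in 0-based
(row, column) pixel coordinates with even-odd fill, numeric thresholds),
with Otsu's method as the scriptable default so the pipeline runs
unattended. Projection precedes masking, matching the macro's order.

Between-group fold changes are ratios of group means of **per-section**
mean intensities; sections, not pixels, are resampled in the percentile
bootstrap CI, because pixels within a section are strongly correlated. A
pixel-pooled aggregation (weighted by masked pixel count) is available,
since published fold-change figures rarely state which aggregation was
used.

The simulator draws an offset rectangular wall lattice (honeycomb-like
wall/lumen proportions, ~30 % wall pixels at the defaults) with programmed
channel intensities, per-voxel Gaussian noise (default sd 5 on an 8-bit
scale), and a focal-attenuation profile over z: the middle slice carries
the full programmed intensity, outer slices are dimmed by 20 %. The
attenuation is what makes the maximum projection meaningful — it selects
the in-focus plane. Were every slice equally bright, the maximum of
independent per-slice noise would add a positive bias of order
$\sigma\,E[\max_z Z]$ to both channels and every group, systematically
shrinking programmed intensity ratios; with a distinct focal plane the
projection is unbiased and a programmed 2.30-fold wall-intensity ratio is
recovered to well within 5 % from 10 sections per group. What the
simulator does not emulate: real point-spread functions, photobleaching,
autofluorescence, and section-to-section biological variability — so
passing tests validate the measurement arithmetic, not robustness to
those effects.

## Group statistics

All scalar readouts funnel into one decision tree at $\alpha = 0.05$:

1. **Gate** — every group passes Shapiro–Wilk *and* the groups jointly
   pass Bartlett's test, each at 0.05 (a pooled-residual Shapiro variant
   is a switch). Note the arithmetic of the all-AND gate: with $k$ groups
   it runs $k + 1$ level-0.05 tests, so even perfectly normal data take
   the parametric path only about $0.95^{k+1}$ of the time (~81 % for
   $k = 3$) — a property of this published workflow, not a defect. A
   zero-variance group forces the nonparametric path with a warning.
2. **Parametric path** — one-way ANOVA, then Tukey HSD adjusted pairwise
   p-values. With two groups Tukey reduces exactly to the pooled-variance
   t-test (verified to 1e-6).
3. **Nonparametric path** — Kruskal–Wallis omnibus, then Tukey-type
   all-pairs rank comparisons (Nemenyi: mean-rank differences from the
   joint ranking referred to the studentized range, tie-corrected
   variance). We chose this single-step procedure over Holm-adjusted
   pairwise Wilcoxon tests after measuring both under the complete null:
   Holm on discrete exact Wilcoxon p-values is conservative (family-wise
   error ~0.03 at $k = 4$, $n = 10$), while the Tukey-type contrast sits
   at the nominal 0.05 (0.030–0.051 across simulation seeds) and mirrors
   the Tukey-type relative-effect contrasts customarily used for this
   step. Exact replication of any particular contrast package's adjusted
   p-values is not attempted.
4. **Letters** — compact letter display by insert-and-absorb on the
   adjusted pairwise matrix: groups share a letter iff their adjusted
   $p \ge \alpha$. Letter columns are processed in alphabetical group
   order for determinism; minimal letter count is not guaranteed, but
   consistency with the matrix is verified exhaustively on every call.

`type1_error_sim()` is the validation harness: on null data the
family-wise error of both paths stays within Monte-Carlo error of 0.05
(1000 replicates in the shipped tests).

```{r stats}
d <- gen_grouped_measurements(list(
  list(label = "WT",   dist = "normal", mean = 10, sd = 1, n = 10),
  list(label = "lineA", dist = "normal", mean = 12, sd = 1, n = 10),
  list(label = "lineB", dist = "normal", mean = 15, sd = 1, n = 10)),
  seed = 2)
compare_groups(d)
```

## Derived metrics

`green_density()` is oven-dry mass over water-saturated volume (volume =
mean of three micrometer thickness readings × measured area; mg mm$^{-3}$
× 1000 = kg m$^{-3}$; no shrinkage correction). `percent_change()` is the
$(x - x_{ctrl})/x_{ctrl} \times 100$ convention behind statements like
"+37 % glucose release" or "−29 % lignin".

## Problem sizes, tolerances and degenerate inputs

The shipped test suite uses sizes a desk check can afford and states them
as its own choices: 9-point isotherms; full-cycle DVS traces of ~7000
samples at 10 s resolution; 5-bin distributions on ~10⁴-sample
thermograms at 1 s resolution; 64×64×3 image stacks, 10 sections per
group, 50 bootstrap-coverage replicates; 1000-replicate null simulations
for the error-rate checks. Numerical policy: strict domain validation at
every entry point ($a_w \in [0,1)$, $T_m < T_0$, positive masses);
trapezoidal integration; negative endotherm areas clipped with a warning;
fit multi-starts keep the best residual sum of squares and report a
convergence flag rather than failing silently; ties at the peak-activity
hold go to the sorption branch; zero observed values are excluded from
MRD. Known limitations are flagged inline above: no diffusion kinetics,
no supercooling, no PSF/photobleaching, no two-way designs or FDR
control, and all schedule-dependent thermoporosimetry results are
relative to the configured hold program.
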