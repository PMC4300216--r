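---
title: "Calibration-set bias in pollen-based temperature reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-set bias in pollen-based temperature reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenclim)
```

## The problem

Transfer functions infer past climate from fossil pollen by calibrating,
over space, the relationship between modern pollen assemblages and modern
climate, then applying that mapping down-core. The method assumes the
pollen–climate relationship is stationary in time. Where humans have
reorganized vegetation independently of climate — as Euro-American land
clearance did across the North American Midwest from the mid-1800s — a
conventional calibration set built from core-top pollen and late
20th-century climate normals encodes both climate *and* land use. Applied
to pre-disturbance fossil pollen, such a set can systematically misstate
past temperatures (typically warm-biased, because a vegetation lagging
rapid modern warming, further depleted in warm-indicator taxa by
disturbance, maps old assemblages onto too-warm climates) and attenuate
the low-frequency climate signal. `pollenclim` packages the full
diagnostic tool-kit for this problem: WA-PLS transfer functions, two
cross-validators, analog screening, a hindcasting experiment that
measures the bias directly, and reconstruction-versus-instrumental
comparison statistics — together with a synthetic-data module that makes
every stage testable against known truth.

## The WA-PLS model

Let $y_{ik}$ be the pollen value (percent) of taxon $k$ at site $i$,
$y_{i+}$ and $y_{+k}$ the row and column sums, $w_i = y_{i+}/y_{++}$ the
site weights, and $x_i$ the climate variable (here monthly mean
temperature, °C). Weighted-averaging partial least squares extracts
components sequentially from the current residual $r_i$ (initialized to
$x_i$):

1. taxon scores $u_k^{(a)} = \sum_i y_{ik} r_i / y_{+k}$;
2. site scores $s_i^{(a)} = \sum_k y_{ik} u_k^{(a)} / y_{i+}$;
3. $s^{(a)}$ is orthogonalized against earlier components under the
   weights $w$ and standardized to weighted mean 0, sd 1 (the transform
   is stored so unseen samples can be scored without the training data);
4. $x$ is regressed on components $1..a$ by weighted least squares and
   $r$ is set to the residuals.

Predictions are $\hat x = \beta_0 + \sum_a \beta_a s^{(a)}$. Deshrinking
is implicit in the final regression (inverse style); there is no separate
deshrinking step. Because percentage rows all sum to 100, the site
weights are equal and a one-component fit coincides exactly with
classical weighted averaging plus inverse deshrinking — the package keeps
an independently coded WA estimator (`fit_wa_inverse()`) and the test
suite verifies the equivalence to 1e-8. Two components (`n_components =
2`, WA-PLS2) is the default, the standard choice for pollen–temperature
work; pollen percentages enter untransformed by default, with a
`sqrt_transform` switch since practice varies.

Scoring is invariant to multiplying a sample by a positive constant, so
proportions and percentages give identical predictions. Taxa whose
training column is entirely zero are dropped with a warning; a component
whose site-score spread falls below 1e-12 aborts the fit with an error
naming the component (this is what a gradient-free calibration set looks
like numerically).

## Cross-validation

`loo_cross_validate()` refits the model once per site and predicts the
held-out site, giving RMSEP_loo alongside the apparent RMSE of the full
fit. `bootstrap_rmsep()` resamples sites with replacement `n_boot` times
(default 1000), predicting the out-of-bag sites each cycle, and
decomposes the error into $s_1$ (root mean square of the per-site sd of
out-of-bag predictions — sampling variability) and $s_2$ (root mean
square of mean out-of-bag prediction minus observed — systematic error),
with $\mathrm{RMSEP}_{boot} = \sqrt{s_1^2 + s_2^2}$. A site that ends up
out-of-bag fewer than twice raises an error advising a larger `n_boot`.

## Analog screening

`squared_chord_distance()` implements
$d(p,q) = \sum_k (\sqrt{p_k} - \sqrt{q_k})^2$, the standard pollen
dissimilarity. Distances are computed on the percent scale (0–200), the
scale on which published minimum-distance series are reported; a
`proportion` switch yields values 100× smaller. Squared chord is
symmetric and zero only at identity, but it is not a metric (no triangle
inequality), and the package reports raw distances without imposing a
no-analog threshold — published thresholds vary and the decision is the
analyst's. Era summaries (`era_mean_min_distance()`) select samples by
age-interval midpoint; ties in nearest-site lookup go to the first site
in file order (logged).

## The hindcasting experiment

`bias_experiment(cal_ref, cal_alt, ...)` fits a transfer function on the
alternative set (e.g. a disturbed modern set), applies it to the
reference set's pollen (e.g. a pre-settlement set), and compares the
residuals — predicted minus observed, so positive means warm bias —
against the reference set's own leave-one-out and bootstrap errors. The
headline summary is `improvement_percent()`, $100\,(\mathrm{RMSE}_{hind}
- \mathrm{RMSEP}_{boot})/\mathrm{RMSEP}_{boot}$, rounded to the nearest
integer: how much worse cross-era prediction is than within-era
cross-validation. The observed climate used for the reference residuals
is the reference set's own climate table; with synthetic data that
pairing is exact, and the disturbance scenario's `climate_offset` lets
the imperfect pairing of real era-straddling normals be emulated too.

## What the synthetic generator emulates

`make_species_pool()` draws taxa with unimodal (Gaussian) responses to
each climate variable, multiplied across variables — the canonical
species-response model behind weighted averaging. The generator's
defaults are the package's fixed study conditions:

* **24 taxa, 300 grains per sample.** A typical upper-midwest pollen sum
  and taxon breadth; counts are multinomial, which is the right noise
  floor for percentage data.
* **Gradients: February −18 to −6 °C, May 8 to 18 °C**, sampled along a
  latent regional gradient with 0.5 °C site scatter, so the two monthly
  variables co-vary across sites as they do geographically. 133
  calibration sites.
* **Response tolerances 1–4 °C, heights log-uniform on [0.5, 2]**; taxa
  assigned round-robin to ruderal/arboreal/herb groups.
* **Disturbance scenario: ruderal ×3, arboreal ×0.6, herb ×0.8**, with
  climate normals warmed by +2.07 °C (February) and +1.57 °C (May) —
  the direction and order of magnitude of post-settlement land
  clearance and of the warming between early-instrumental and modern
  30-year normals. The disturbed pollen is generated from the
  *undisturbed-era* climate: vegetation is assumed not to have
  equilibrated to the warming, which is precisely the non-stationarity
  the hindcast experiment is designed to detect. Under these conditions
  the expected hindcast bias is approximately the injected climate
  offset.
* **Climate history AD 1116–2002**: MCA baseline (February −11.5 °C, May
  13.3 °C), LIA 1450–1850 at −1.0 °C, a post-1850 linear ramp of
  +2.0 °C, interannual white noise sd 1.0 °C; down-core sampling at
  4-year varve intervals (a trailing shorter interval is kept and
  logged).

Features of real data the generator deliberately does **not** emulate:
spatial autocorrelation among sites, pollen dispersal and taphonomy,
pollen-production lags and inter-annual carry-over (so the strong
high-frequency variance attenuation of real pollen records is *not*
reproduced — synthetic reconstructions track interval-mean climate
closely), secondary gradients beyond the two temperature variables, and
errors-in-variables in the calibration climate. Passing tests therefore
demonstrate the correctness and internal consistency of the estimators
and the directional logic of the bias/analog experiments, not the error
magnitudes to be expected from field data.

## Comparison statistics

`align_to_intervals()` averages annual instrumental values over each
reconstruction sample's inclusive year interval — the instrumental
record is cumulatively averaged exactly as the pollen samples were
according to the varve counts; partially covered samples are dropped with
a message. The mean test defaults to Welch's unequal-variance $t$: an
interval-averaged reconstruction typically has a small fraction of the
instrumental variance, and with 15-per-group comparisons the
Welch–Satterthwaite degrees of freedom (≈15 under strong variance
inequality, ≈28 when variances match) are the internally consistent
choice; `var_equal = TRUE` restores pooled Student's $t$. The variance
$F$-test is two-sided by doubling the smaller tail and is also available
from summary standard deviations alone
(`variance_f_test_summary()`), for recomputing published tables.
`ols_trend()` reports the slope, the total change over an annual record
($\mathrm{slope} \times (n-1)$ years), and the slope $t$-test on $n-2$
degrees of freedom. `variance_captured()` reports
$100\,\mathrm{var}(\mathrm{rec})/\mathrm{var}(\mathrm{instr})$ over
aligned pairs; note that published "variance captured" figures are not
always consistent with the ratio of reported group standard deviations,
so the package implements the explicit variance-ratio definition only.
`extend_series_by_regression()` builds an extended station record by OLS
on an overlapping reference station, filling only missing years and
keeping observed values verbatim, reporting the overlap's adjusted $r^2$.

## Numerical choices and degenerate inputs

* Percent rows are accepted within ±0.5 of 100 on file input (legacy
  rounding) and renormalized with a warning; internally generated
  matrices are held to 1e-6.
* Taxon matching is exact after whitespace trimming and case-folding; no
  synonym resolution (curator work, out of scope). Duplicate names after
  case-folding are an error.
* Age intervals are calendar years AD, inclusive on both ends: a 4-year
  sample "AD 1820–1823" covers four instrumental years.
* All-zero pollen rows are errors naming the sample, in conversion,
  scoring and exclusion alike.
* Every stochastic function takes an explicit integer seed and restores
  the caller's RNG state; identical seeds give bit-identical output.
* Paired $t$ on constant differences returns $t = 0$ (all-zero) or
  signed infinity rather than NaN; an exactly linear trend reports
  $p = 0$ on a guarded path.

## Problem sizes in the test suite

The suite validates estimator equivalences on small random sets (10–25
sites), parameter recovery on the full 133-site default with a 5-seed
sweep, and the bias-direction and analog-direction experiments over 20
seeds with 200 bootstrap cycles per seed — enough for the RMSEP
estimate, whose bootstrap standard error is well below the effects being
measured, while keeping the default `n_boot = 1000` for analysis use.

## Known limitations

WA-PLS is the only transfer-function family implemented; the analog
module screens calibration quality but does not reconstruct climate by
analog matching (MAT-as-estimator). Bootstrap sample-specific error bars
beyond $s_1$ are not provided. The generator's disturbance acts
uniformly across sites; spatially structured disturbance, which produces
the "non-random residual structure" seen in real hindcasts, is not
modelled, so residual-structure diagnostics are limited to summary
statistics.
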