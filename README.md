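# pollenclim

Pollen–climate transfer functions and calibration-set bias diagnostics.

## The problem

Pollen-based climate reconstruction calibrates, over space, the
relationship between modern pollen assemblages and observed climate, and
applies that transfer function down-core. This assumes the
pollen–climate relationship is stationary in time. In regions of heavy
historical land use (the North American Midwest, much of Europe) it is
not: land clearance inflated ruderal taxa such as *Ambrosia* at the
expense of the native arboreal flora, and vegetation lags rapid modern
warming, so a conventional calibration set built from core-top pollen
and late 20th-century climate normals encodes land use as well as
climate. Reconstructions made with such a set can carry a systematic
warm bias of order 1 °C and attenuate centennial-scale signal — enough
to misstate Little Ice Age temperatures and understate regional
anthropogenic warming.

`pollenclim` is for palynologists and palaeoclimatologists who want to
build transfer functions *and* stress-test them: cross-validate within a
calibration set, screen analog quality against a fossil record, hindcast
one era's transfer function onto another era's pollen to measure
non-stationarity bias directly, and compare down-core reconstructions
with early instrumental records.

## What is inside

* **Transfer functions** — weighted-averaging partial least squares
  (WA-PLS). With $y_{ik}$ the percentage of taxon $k$ at site $i$ and
  $x_i$ the climate value, each component takes taxon scores
  $u_k = \sum_i y_{ik} r_i / y_{+k}$, site scores
  $s_i = \sum_k y_{ik} u_k / y_{i+}$, orthogonalizes and standardizes
  $s$ under the site weights, and regresses $x$ on all components by
  weighted least squares, carrying the residual $r$ forward
  (deshrinking is implicit in the regression). `fit_wapls()`,
  `predict()`, `loo_cross_validate()`, `bootstrap_rmsep()` (with the
  $s_1$/$s_2$ error decomposition), JSON model serialization.
* **Analog screening** — squared chord distance
  $d(p,q) = \sum_k (\sqrt{p_k}-\sqrt{q_k})^2$ on the percent scale,
  minimum-distance series against a calibration set, era summaries.
* **Hindcasting** — `bias_experiment()` fits on one calibration set,
  predicts another era's pollen, and contrasts the hindcast RMSE with
  the reference set's own leave-one-out and bootstrap RMSEP
  (`improvement_percent()`).
* **Comparison statistics** — interval-averaging of instrumental series
  onto varve-dated sample intervals, Welch/Student $t$, two-sided $F$ on
  variances (also from published summary sds), paired $t$, OLS trend,
  5-point moving average, period means, variance captured, and
  regression-based extension of short station records.
* **Synthetic data** — Gaussian (unimodal) taxon–climate response pools,
  multinomial count noise, land-clearance disturbance scenarios, a
  last-millennium climate history (MCA / LIA / post-1850 warming), and
  varve-dated down-core records with aligned ground truth.
* **I/O** — plain-CSV pollen matrices, climate tables, fossil records,
  instrumental series; taxonomic harmonization; taxon-exclusion
  sensitivity transforms. A thin command-line front end
  (`inst/cli/pollenclim`) exposes `simulate`, `fit`, `reconstruct`,
  `analogs`, `bias` and `compare` subcommands.

## Worked example

Build a synthetic world with a known +2.07 °C February offset between
the two calibration eras, then measure what a conventional "modern"
calibration set does to a pre-settlement record:

```r
library(pollenclim)

pool <- make_species_pool(24, seed = 1)
cal  <- generate_calibration(pool, n_sites = 133, seed = 2)  # "1870" set
mod  <- apply_disturbance(cal, disturbance_scenario(), seed = 3)

tf <- fit_wapls(cal, "feb_mean_temp")
tf
#> WA-PLS transfer function: feb_mean_temp, 2 component(s), 24 taxa
#> apparent RMSE: 0.3536 degC

loo_cross_validate(cal, "feb_mean_temp")
#> WA-PLS cross-validation (loo), feb_mean_temp:
#>   RMSE_app  0.3536 degC
#>   RMSEP_loo 0.3761 degC

bias_experiment(cal, mod, "feb_mean_temp", n_boot = 500, seed = 4)
#> hindcast bias report (feb_mean_temp), n = 133 sites
#>   mean bias   1.872 degC
#>   residual sd 0.6659 degC
#>   RMSE        1.986 degC
#>   reference RMSEP_boot 0.3979 degC; bootstrapped improvement 399%
```

The hindcast mean bias (+1.87 °C) recovers the injected calibration
offset: the disturbed-modern transfer function reconstructs
pre-settlement pollen almost 2 °C too warm, and its cross-era error is
five times the reference set's own bootstrap RMSEP. The same asymmetry
shows up in analog space and down-core:

```r
hist <- climate_history(seed = 5)
dc   <- generate_downcore(pool, hist, seed = 6)

era_mean_min_distance(min_analog_series(dc$record, cal), 1116, 1849)
#> [1] 3.28   # pre-disturbance samples find close analogs in the 1870 set
era_mean_min_distance(min_analog_series(dc$record, mod), 1116, 1849)
#> [1] 13.11  # and poor analogs in the disturbed modern set

rec_1870 <- reconstruct(tf, dc$record)
rec_mod  <- reconstruct(fit_wapls(mod, "feb_mean_temp"), dc$record)
period_mean(rec_1870, 1116, 1876)   # -12.10 degC  (truth: -12.03)
period_mean(rec_mod,  1116, 1876)   # -10.93 degC  (warm-biased)
```

The pre-settlement-calibrated reconstruction tracks the true
interval-mean history to within 0.1 °C over AD 1116–1876; the
modern-calibrated one runs more than 1 °C warm, which would translate
directly into an overestimated LIA and an underestimated warming since.

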