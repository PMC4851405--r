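# phenolag

Lagged soil-moisture and day-length modelling of savannah leaf phenology.

Savannahs cover roughly half of the world's terrestrial area, and their
greening is water-limited: leaves flush days to weeks after the soil
recharges, modulated by photoperiod. `phenolag` is an R package for the
statistical pipeline that turns per-site climate records and satellite
greenness (NDVI) into such a model, for researchers in remote-sensing
phenology and land-surface modelling:

* **Preprocessing** — NDVI composites (16-day, jittered acquisition dates)
  are gap-filled, resampled to an 8-day grid, and smoothed with an
  adaptive Savitzky–Golay filter (7-step degree-2 window, switching to a
  3-step window wherever a raw neighbour difference exceeds 0.08 NDVI so
  genuine rapid green-up survives). Daily climate is aggregated to the same
  grid: 8-day median volumetric soil moisture and maximum day length
  (computed from latitude and date).
* **Model selection** — exhaustive search over all lagged candidates

  NDVI_t = b0 + b1 · log(sm_{t−l1} · MAP) + b2 · dayL_{t−l2} + e,

  with at most one soil-moisture term (log(sm) or log(sm·MAP)) and one
  day-length term, lags 0–10 steps (0–80 days): 275 candidates, fitted by
  pooled OLS across sites, selected by BIC.
* **Variable importance** — per-site decomposition of r² between the
  soil-moisture and day-length lag groups by averaging over regressor-group
  orderings (grouped LMG; exact per-regressor LMG available for small
  designs).
* **Evaluation** — site-holdout cross-validation (12 train / 3 test,
  repeated) reporting RMSE, r², and variance inflation factors;
  site-count sensitivity curves; start-of-season (midpoint between a
  cycle's peak and preceding minimum) and amplitude phenometrics.
* **Synthetic data** — a seeded generator (pulsed wet-season rainfall into
  a decaying soil bucket, solar day length, a planted lagged log-linear
  NDVI response, composite-style sampling with jitter and gaps) so the
  whole pipeline is testable without downloads.

## Worked example

Simulate 15 sites for 3 years with the canonical planted response
`0.12·log(sm₂·MAP) + 0.01·dayL₂ + 0.22` and observation noise 0.02, run
the full chain, and evaluate:

```r
library(phenolag)

cfg     <- synth_config(n_sites = 15, n_years = 3, noise_sd = 0.02, seed = 1)
sites   <- generate_ensemble(cfg)
aligned <- lapply(sites, align_site)          # gap-fill, smooth, aggregate

model <- select_model(aligned)                # 275 candidates, BIC
model
#> <candidate_model>
#>   NDVI = 0.1149*log(sm_2*MAP) + 0.01173*dayL_2 + 0.2066
#>   n = 1956, r2 = 0.963, BIC = -14540.8
```

The selection recovers the planted structure — both variables at lag 2
(16 days), soil moisture multiplied by MAP inside the log — with
coefficients near their planted values (the residual deviation is the
smoothing/compositing footprint; on noise-free input recovery is exact to
machine precision, which the test suite asserts).

```r
group_lmg(aligned[[2]])                       # per-site importance
#> <importance_result> site02: sm 58.5%, dayL 41.5% of r2 = 0.982

holdout_cv(aligned, model, n_test = 3, reps = 200, seed = 1)
#> <eval_summary> 200 reps: RMSE 0.024 +/- 0.002, r2 0.96 +/- 0.01, VIF 1.12 +/- 0.03

phenometric_errors(aligned[1:3], model)
#>   site_id sos_error_steps amplitude_error n_cycles_matched
#> 1  site01      -2.3333333    -0.011545243                3
#> 2  site02       0.3333333    -0.005072786                3
#> 3  site03      -1.0000000    -0.034565202                3
```

Reading the numbers: importance splits each site's explained variance
between the two drivers (drier, lower-MAP sites leaning on soil moisture);
the holdout RMSE of 0.024 sits just above the 0.02 noise floor because
coefficients are re-estimated on 12 sites per repetition; VIF ≈ 1.1 says
the two selected regressors are nearly orthogonal; SOS errors are in
8-day steps (negative = model greens up early) and amplitude errors in
NDVI units.

`run_pipeline(pipeline_config(output_dir = "out"))` performs all of the
above and writes plain-text artifacts (`aligned/*.csv`, `model.json`,
`importance.csv`, `eval_summary.csv`, `per_site_metrics.csv`,
`sensitivity.csv`, `run.log`). The same stages are scriptable via the CLI
in `inst/cli/phenolag`:

```sh
phenolag simulate --out raw --seed 1
phenolag preprocess --in raw --out aligned
phenolag select --in aligned --meta raw/metadata.csv --out model.json
phenolag evaluate --in aligned --meta raw/metadata.csv --model model.json --out eval
phenolag run --out out --seed 42        # end-to-end
```

## Documentation

`vignettes/phenolag-methods.Rmd` documents the model and its assumptions,
the synthetic world and its limits, and every numerical convention
(filter edge handling, BIC tie-breaks, cycle segmentation, degenerate
inputs).
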