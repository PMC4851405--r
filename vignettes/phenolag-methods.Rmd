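---
title: "Modelling savannah leaf phenology from lagged climate drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling savannah leaf phenology from lagged climate drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolag)
```

## The model

Savannah greenness tracks water availability with a delay: soil moisture
recharges before leaves flush, and day length modulates the phenological
strategies of trees and grasses. `phenolag` models site-level NDVI on an
8-day grid as a pooled lagged regression

$$
\mathrm{NDVI}_t \;=\; \beta_0 \;+\; \beta_1\,\log(\mathrm{sm}_{t-\ell_1}\cdot \mathrm{MAP})
\;+\; \beta_2\, \mathrm{dayL}_{t-\ell_2} \;+\; \varepsilon_t ,
$$

where `sm` is the 8-day median volumetric soil moisture (%), `MAP` the
site's mean annual precipitation (m/year), `dayL` the 8-day maximum day
length (hours), and $\ell_1,\ell_2$ are lags in 8-day steps. The model
form is not imposed: the search space holds every combination of at most
one soil-moisture term (as $\log(\mathrm{sm})$ or
$\log(\mathrm{sm}\cdot\mathrm{MAP})$) and at most one day-length term,
each lagged 0–10 steps (0–80 days) — 275 candidates at the default bound.
Every candidate is fitted by ordinary least squares on the pooled rows of
all sites and scored with the Gaussian concentrated-likelihood BIC
$n\log(\mathrm{rss}/n) + p\log n$; the lowest-BIC candidate is selected.

Assumptions worth stating explicitly:

* one global equation — a single intercept pooled over sites, no per-site
  effects (this is what makes the model transferable, and what limits it);
* Gaussian, independent residuals at the 8-day scale (no autocorrelation
  correction);
* the soil-moisture response is log-linear, with MAP entering only as a
  multiplicative (hence additive-in-log) site scalar;
* at most one term per variable, so a lag is a point estimate, not a
  distributed response.

## Preprocessing

NDVI arrives as irregular 16-day composites with per-pixel acquisition
dates. The chain is: linear gap-filling resampled to an 8-day grid
anchored at the first acquisition; adaptive Savitzky–Golay smoothing;
8-day median soil moisture and maximum day length aggregated over
half-open daily windows aligned to the same grid.

The smoother fits a degree-2 polynomial over a 7-step window. Points whose
*raw* value differs from either temporal neighbour by more than 0.08 NDVI
are refitted with a 3-step window, which for three points is exact
interpolation — rapid green-up, a real feature of savannahs, is left
untouched rather than smoothed away. Two numerical choices:

* **Edges.** We fit the same polynomial on the truncated window and
  evaluate it at the edge point (the `mode = "interp"` convention), rather
  than reflect-padding. Reflection of a general linear or quadratic series
  is no longer that polynomial, so reflect-padding breaks exact
  reproduction of low-order polynomials at the series ends; truncated-window
  fitting preserves it everywhere, which is also what the test suite
  asserts to 1e-10.
* **Jump detection** runs on the raw series against both neighbours
  (either-neighbour exceedance), before any filtering.

Day length uses the Cooper declination
$\delta = 23.44^\circ \sin(2\pi(284+\mathrm{doy})/365)$ with hour angle
$\omega = \arccos(-\tan\phi\tan\delta)$ clamped for polar cases; it agrees
with a Spencer-declination oracle to under 0.2 h at mid latitudes.

Candidate drivers can be screened before modelling: per-site Pearson
correlations with NDVI are averaged across sites, and within any candidate
pair whose mean mutual $|r|$ exceeds 0.7 the member with the weaker NDVI
correlation is dropped (minimum temperature is the canonical casualty —
it duplicates day length).

## The synthetic world

No observational data ship with the package; a generator produces site
ensembles with the statistical structure the analysis assumes, so every
stage is testable offline. Its defaults are fixed once:

| knob | default | rationale |
|---|---|---|
| sites × years | 15 × 3 | the study design being emulated |
| latitude | U(−26°, 40°) | span of savannah flux sites on four continents |
| MAP | U(0.3, 1.2) m/yr | semi-arid to dry sub-humid |
| wet season | DOY 152–273 (mirrored S hemisphere) | ~4-month monsoon |
| rainfall | Poisson events, 0.3/day × Exp(12 mm) | ~440 mm/yr |
| bucket | decay 0.04/day, capacity 45 vol%, residual 3 vol% | surface-layer dynamics; residual water content keeps log finite and NDVI in a realistic 0.3–0.85 band |
| response | 0.12·log(sm₂·MAP) + 0.01·dayL₂ + 0.22 | the canonical two-term, lag-2 structure |
| noise | sd 0.02 NDVI | a guess; no satellite noise magnitude is stated anywhere we could adopt |
| sampling | 16-day composites, jitter ≤ 8 days, 5% gaps | composite acquisition-date behaviour |

Soil rain depth converts to volumetric % over a fixed 300 mm surface
layer. Soil moisture starts at half capacity.

One construction detail matters. The daily latent NDVI applies the planted
lagged functional to **rolling 8-day leading-window aggregates** (median
sm, max dayL) of the daily climate. On *any* 8-day grid this collapses
exactly to the regression the selection stage fits, so a noise-free
ensemble is a fixed point of the pipeline: the selected model reproduces
the planted terms, lags and coefficients to machine precision, and
acquisition-date jitter shifts the analysis grid without distorting the
planted response. A pointwise daily response could not satisfy this —
the preprocessing median/max aggregation would already perturb it.

What the generator does **not** emulate: cloud/QA contamination and
view-angle effects in real composites, tree–grass mixtures with distinct
cycles, inter-annual rainfall trends, soil-type differences in the
moisture–greenness coupling, grazing or fire. A green test therefore
establishes internal correctness of the pipeline on data obeying the
model's assumptions — not that the model is right for any particular
savannah.

## Importance, evaluation, phenometrics

**Relative importance.** Per site, the $r^2$ of NDVI on
{log sm lags 0–10} ∪ {dayL lags 0–10} is decomposed by averaging
incremental contributions over regressor-group orderings. With two groups
the average is closed-form:
$I(A) = \tfrac12[R^2(A) + R^2(A\cup B) - R^2(B)]$, and
$I(A)+I(B)=R^2(A\cup B)$ exactly. Soil moisture enters as log(sm) without
MAP: within a site MAP is constant, so the choice shifts only the
intercept and cannot change any $R^2$ (asserted as a test property). The
classical per-regressor decomposition (`individual_lmg`, exact via the
$2^m$-subset identity) is retained for designs up to 12 columns as an
oracle; its per-group sums coincide with the grouped form. Two caveats:
with correlated groups an *idle* group still receives half of the shared
explained variance, so a soil-moisture-only world yields 100% soil-moisture
importance only when day length is decorrelated from soil moisture; and at
finite series length the 11 idle lags chance-fit a little variance, giving
a ceiling of $100\cdot(1 - R^2_{\text{chance}}/2)$ that approaches 100%
as the record lengthens.

**Evaluation.** Site-holdout cross-validation refits the *fixed* selected
structure on random training subsets (default 12 of 15 sites) and scores
the pooled holdout rows: RMSE, $r^2$, and the mean variance inflation
factor of the holdout design (VIF of each regressor on the others;
computed on the evaluation subset, matching where the quantity is
reported). Holdout $r^2$ is squared Pearson correlation by default; the
$1-\mathrm{SSE}/\mathrm{SST}$ form is available behind `r2_method =
"rss"`. Site-count sensitivity refits on k random sites and records
*in-sample* pooled RMSE — with heterogeneous sites this is the choice that
produces the characteristic rising-then-saturating curve, because few
sites can be fitted closely and many cannot.

**Phenometrics.** Growing cycles are delimited by local minima; a cycle
counts if its peak rises at least 35% of the site amplitude (max − min of
the whole series) above the preceding minimum — the prominence threshold
and cycle segmentation are package conventions, configurable, since only
the within-cycle rule is canonical. Start of season is the rising-limb
index whose value is nearest the (minimum + peak)/2 midpoint, ties to the
earlier step; modelled series are re-smoothed with the same filter before
comparison so both series carry the same filter bias. Indices are 1-based
(R convention); CSV artifacts identify steps by date, and SOS *errors*
(model − observed, in 8-day steps) are index differences and therefore
convention-free.

## Numerical choices

* Rank-deficient designs are an error in `fit_ols` (distinct from
  near-collinearity, which is fitted and reported via VIF); subset-$R^2$
  computations in the importance module tolerate rank deficiency, where it
  is benign.
* `rss = 0` maps to a BIC of $-\infty$; `select_model` additionally snaps
  rss below $10^{-12}\sum y^2$ to zero so that, on noise-free data, the
  parsimony tie-break (fewer parameters, then smaller total lag) decides
  among numerically perfect fits instead of floating-point dust.
* Per-candidate designs drop each site's first max-lag steps, so candidate
  sample sizes differ by up to 10 rows per site; at the pooled sizes in
  use this BIC discrepancy is negligible.
* Soil moisture is floored at 0.1 vol% so log transforms stay finite even
  when the residual-moisture floor is disabled.
* All resampling (holdout, sensitivity, generation) is plain-R RNG under
  explicit seeds; per-site streams are derived from the config seed so
  individual sites are reproducible in isolation.

## Known limitations

* Adjacent day-length lags correlate at ~0.99 on the 8-day grid, and the
  day-length contribution (0.01 per hour over a few hours' seasonal range)
  is comparable to the observation noise. On *unsmoothed* grid data the
  exact day-length lag is misidentified by ±1 step in roughly a tenth of
  replicates at noise sd 0.02; running the full pipeline — whose smoothing
  step roughly halves the effective noise — makes recovery essentially
  certain at the default design. The soil-moisture lag, carrying most of
  the signal, is robust throughout.
* The pooled single-intercept model cannot represent site-level offsets;
  on heterogeneous ensembles this surfaces as a rising sensitivity curve
  and inflated per-site RMSE, which is the intended diagnostic, not a bug.
* Cycle matching for SOS comparison is greedy nearest-peak; series with
  very different cycle counts are matched only on the overlap.
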