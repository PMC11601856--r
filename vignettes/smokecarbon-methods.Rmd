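---
title: "Estimating fire-smoke carbonaceous PM2.5 with a residual-adjusted super learner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fire-smoke carbonaceous PM2.5 with a residual-adjusted super learner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokecarbon)
```

## The problem

Wildland-fire smoke loads the atmosphere with carbonaceous fine
particulate matter -- organic carbon (OC) and elemental carbon (EC).
Chemical-transport models (CTMs) can simulate these species daily over a
continent, and a *paired* simulation -- one run with all emissions
("smoke-on") and one identical run with fire emissions removed
("smoke-off") -- isolates the fire contribution.  But raw CTM speciation
is coarse and biased, while ground monitors are sparse.  `smokecarbon`
calibrates the paired CTM fields against monitor observations to produce
full-coverage daily estimates of *background*, *total*, and *smoke*
OC and EC, and then carries those estimates through to population
exposure (heavy-fire-smoke person-days) and health-burden accounting
(attributable non-accidental deaths and their monetized value).

Because the real inputs (continental CTM archives, speciation-network
observations, population rasters) cannot be redistributed, the package
includes a first-class synthetic-data generator with known ground truth.
Every downstream stage is developed and tested against that truth.

## The three-level model (RASL)

For each species (OC, EC) and each smoke scenario (on, off) the
estimator is a three-level *residual-adjusted super learner*:

1. **Base learners.** Four heterogeneous regressors -- random-forest
   trees (`ranger`), gradient-boosted trees (`xgboost`), elastic-net
   penalized linear regression (`glmnet`), and k-nearest-neighbour
   regression (`caret::knnreg`) -- are each fit with k-fold
   cross-validation (default k = 5).  Every training row receives an
   *out-of-fold* (OOF) prediction from a model that never saw it.
   Heterogeneity across families is the point: stacking only helps when
   the base learners err differently.
2. **Meta-learner.** The OOF predictions are combined by non-negative
   least squares with a free intercept (Lawson--Hanson NNLS on a design
   augmented with +1/-1 intercept columns).  Because every single base
   learner is a feasible solution, the fused OOF fit can never be
   meaningfully worse than the best single learner -- a property the
   test suite asserts (`fused R^2 >= best base R^2 - 0.01`).
   A rank-deficient OOF matrix falls back to a ridge-stabilized solve
   with a warning.
3. **Residual smoother.** Daily fused predictions are averaged to
   monthly means; the residual `r = obs_month - pred_month` at monitor
   cells is modelled as `r ~ te(x, y, k = c(5, 5)) + s(month, k = 6)`
   with `mgcv::gam` and GCV-chosen smoothing.  The adjustment is applied
   at the monthly (and hence annual) scale only; daily fields remain the
   level-2 output.  Adjusted concentrations are clipped at zero.

Features are the scenario-matched CTM concentration (the smoke-on run
feeds smoke-on rows, the smoke-off run feeds smoke-off rows), an
AOD-like satellite layer, two meteorology-like layers, static
urbanization and elevation layers, and coordinate/time terms
(x, y, day-of-year, year).  Feature standardization constants are
computed on observed rows only and reused at prediction time.

### Skew handling (SMOTE for regression)

Concentration distributions are strongly right-skewed, and the rare high
values matter most.  Classic SMOTE is a classification tool; the package
adapts it to regression by interpolating the *label jointly with the
features*: a minority row (label above the 0.9 label quantile by
default) is combined with one of its k = 5 nearest minority neighbours
in standardized feature+label space using a uniform lambda in (0, 1), so
every synthetic label lies between its parents' labels.  Synthetic rows
are flagged, may train levels 1--2, and are excluded from every reported
metric.  SMOTE is applied after the scenario split (both orderings are
possible in principle; after-split keeps each scenario's tail density
independent).

### Scenario classification

A cell-day is smoke-impacted when the coarse-to-fine mapped difference
`ctm_on - ctm_off` (OC+EC summed) strictly exceeds a threshold `delta`,
default 0.1 ug/m3.  The difference is kept unfloored so the threshold
acts on the signed field; the strict inequality makes `delta = 0`
classify exactly the positive contributions.  The coarse-to-fine map is
nearest-assignment (each fine cell takes its containing coarse cell's
value) -- interpolation would invent sub-grid structure the CTM does not
have.  `delta` is deliberately a configuration knob: it is the natural
sensitivity-analysis axis for the whole pipeline.

### Outlier exclusion

Monitor values strictly above fixed per-species caps (OC 34.75, EC
7.40 ug/m3 -- the 99.98th-percentile convention for these networks) are
removed before training; a `recompute_percentile` mode derives caps from
the data instead.  Fixed caps are the default for determinism.

## The synthetic world

`simulate_truth()` generates what the estimator must cope with, not what
makes it look good:

* **Background**: a spatially autocorrelated lognormal surface
  (separable Gaussian-kernel smoothing of white noise, correlation
  length 8 cells) with an AR(1) day-to-day perturbation (rho = 0.6), a
  winter-peaking seasonal cycle (amplitude 0.35), and an urban uplift.
  Mean levels: OC 1.2, EC 0.30 ug/m3.
* **Smoke**: episodic plumes (Poisson ignitions, 0.6/day across the
  domain, seasonally modulated to peak in mid-September), each a
  truncated Gaussian kernel (sd 3 cells, hard cut at 3 sd so smoke is
  *exactly* zero outside footprints) that drifts and decays over a
  geometric lifetime (mean 3 days).  OC and EC share events with a 3:1
  intensity ratio, matching the dominance of organic carbon in smoke.
* **CTM pair**: block means at a 4x coarsening, background bias 1.2,
  smoke bias 0.6, *shared* additive noise between the paired runs
  (they differ only in fire emissions, so their errors are common),
  multiplicative noise on the smoke component (sdlog 0.2), and a small
  independent pair noise (0.02 ug/m3).
* **Monitors**: 200 sites placed preferentially in urban cells,
  co-located for both species, reporting every third day (the 1-in-3
  cadence of speciation networks), with species-specific Gaussian
  measurement noise (OC 0.25, EC 0.08 ug/m3 -- uncertainty scales with
  the species' concentration range) and clipping at zero.
* **Auxiliaries**: an AOD-like layer correlated with total concentration
  with 30% of cell-days missing at random (cloud gaps; flagged `NA`,
  never silently imputed), two meteorology-like layers, static
  urbanization and elevation.
* **Population**: clustered weights raised to an exponent (default 2),
  allocated by largest-remainder rounding so cell counts sum exactly to
  the requested total.

What the generator does *not* emulate: atmospheric transport and
chemistry, real geography, network-specific measurement protocols,
long-range plume morphology, or spatially correlated AOD missingness.
Passing tests therefore demonstrate that the pipeline recovers a truth
*of this structural class* -- seasonal, skewed, episodic,
urban-gradient -- not that it reproduces any real-world concentration
field.

The simulation calendar uses 365-day years (no leap days), so every year
is structurally identical; July 1st is day-of-year 182.

## Cross-validation and metrics

Three schemes evaluate the stack, always on observed rows only:

* `random_cv()`: rows into 10 uniform folds (sizes differ by at most 1).
* `spatial_cluster_cv()`: sites k-means-clustered on coordinates (k = 10,
  20 restarts, fixed seed); a whole cluster is held out together,
  emulating the loss of a regional network.  `k = #sites` degenerates to
  leave-one-site-out.
* `temporal_loyo_cv()`: each year held out in turn.

Metrics are R^2 = 1 - SSE/SST, RMSE, and the OLS slope of observed
regressed on predicted (the regression direction is a convention and is
stated here because conventions differ).  Daily pairs are aggregated to
site-months (requiring >= 4 daily pairs) and site-years (>= 20 daily
pairs) for monthly and annual metrics; these minimums guard against
unstable means and are configuration knobs.  Permutation importance
reports the mean in-sample R^2 drop over 5 permutations per feature.

Within `fit_base_learners()` folds are assigned by a deterministic hash
of (site, day) and rows are internally sorted by key before training, so
out-of-fold values are invariant to the order in which rows arrive.

## Exposure and burden accounting

`decompose_concentrations()` defines background = smoke-off model
everywhere; total = smoke-on model on smoke-impacted cell-days and
background elsewhere; smoke = max(0, total - background), exactly zero
on smoke-off cell-days.  A *heavy-fire-smoke grid-day* has total
carbonaceous (OC+EC) concentration strictly above 1 ug/m3 with smoke
strictly above 50% of the total.  Person-days are population-weighted
counts of heavy cell-days, accumulated within calendar years; period
summaries average the within-year cumulative value across a period's
years, and per-capita days divide by total population.  "Smoke days"
for the frequency map are smoke-impacted (classified) cell-days; a
concentration-based alternative is available in configuration.

Two burden pathways are implemented:

* **Bin-rate** (CONUS-style): monthly non-accidental mortality rates per
  concentration bin, annualized by multiplying by 12, looked up by each
  cell's annual-mean smoke carbonaceous concentration, times population
  / 100,000, booked to the year after exposure (a no-lag variant exists
  for sensitivity).  The shipped schedule
  (`inst/extdata/rate_schedule_synthetic.csv`) is synthetic: the real
  epidemiological schedule is not public, so applications must supply
  their own CSV.  Deaths are reported unrounded internally and rounded
  only at the region-year reporting level.
* **CRF** (log-linear, AQBAT-style): attributable fraction
  `AF = 1 - exp(-beta * dC)`, deaths = AF x baseline rate x population
  / 100,000.  Default beta 0.0077 per ug/m3 corresponds to a relative
  risk of about 1.08 per 10 ug/m3 of chronic exposure, a conventional
  magnitude for PM2.5 mortality; baseline 700 deaths/100,000/yr.  Both
  are explicit synthetic defaults, not estimates.

Monetization multiplies deaths by a year-specific value of statistical
life, `VSL_t = VSL_base x (price_t/price_base) x
(income_t/income_base)^elasticity` (income elasticity default 1.0);
currencies are never converted.  Percent changes are reported to the
nearest integer percent and regional shares to one decimal (half-up).

## Numerical and design choices

* Strict inequalities at every threshold (scenario delta, heavy-smoke
  total and fraction, outlier caps) so boundary values fall on the
  conservative side; all printed definitions use "exceeds"/"more than".
* All published concentrations are clipped at zero after the
  meta-combination and again after residual adjustment.
* The k-NN learner caps its reference set at 5,000 rows (seeded
  subsample): brute-force neighbour search over millions of prediction
  rows would otherwise dominate runtime, and the learner's meta-weight
  is insensitive to the cap.
* The random-forest learner runs 100 trees with minimum node size 50
  and 63.2% subsampling -- at these training sizes deeper forests change
  the fused prediction negligibly while tripling cost.
* Monthly residual fitting drops monitor-months with fewer than 4 daily
  values (unstable means) and needs at least 20 monitor-months; the
  spatial basis auto-shrinks with a warning when data cannot support it,
  and the temporal basis is capped by the number of observed months.
* One global seed fans out to per-stage seeds via a fixed affine
  splitter modulo 2^31 - 1; identical configurations are bit-reproducible
  (the pipeline test asserts identical stage hashes).
* Cubes are persisted as long-format CSV (`write_cube_csv()`); monitor,
  schedule and VSL tables as CSV; configurations as YAML.

## Problem sizes

The default configuration -- a 64 x 64 grid, 2 years, 200 monitor sites
on a 1-in-3 cadence -- is the package's reference experiment: large
enough that plumes, seasons and urban gradients all express themselves,
small enough to run end to end in a few minutes on one CPU.  Unit tests
use a 16 x 16 / 120-day world.  The spatial scale of the reference
experiment is a deliberate stand-in for a continental 1-km grid: the
estimator is coordinate-frame agnostic, so nothing but memory changes
with domain size.

## Known limitations

* The scenario rule thresholds the summed OC+EC contribution; whether
  the original classification thresholded species separately or used
  satellite plume flags is not public, so the rule is parameterized
  rather than guessed.
* The four base-learner families and the meta-learner identity of the
  original framework are likewise not public; the defaults here are
  declared package choices.
* SMOTE's regression adaptation (joint feature+label interpolation,
  minority = top decile) is a package design; other adaptations exist.
* Person-day accounting uses an annual population snapshot, not
  daily-varying population.
* The burden magnitudes produced by the synthetic defaults are
  arithmetic demonstrations, not estimates: the rate schedule, CRF
  coefficient and VSL indices are synthetic placeholders.
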