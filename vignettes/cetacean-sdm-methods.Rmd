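---
title: "Methods: simulating and comparing cetacean species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing cetacean species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cetsdm` implements a complete, testable version of a standard analysis
chain for shipboard cetacean surveys in an eastern-boundary upwelling
system: systematic line-transect effort is cut into ~5-km modeling
segments, detection-corrected effective areas are attached, and three
species-distribution-model (SDM) families are fitted and compared — a
density generalized additive model (GAM), a presence/absence GAM, and a
presence/absence boosted regression tree (BRT) — including validation on
a withheld, anomalously warm survey year. Because multi-decade survey
data and ocean-model reanalyses cannot ship with a package, the first
module is a synthetic-data generator that reproduces the statistical
structure the analysis assumes; every downstream stage is exercised
against it.

# The observation model

Density on segment $i$ follows the standard line-transect identity

$$D_i = \frac{n_i \cdot s_i}{A_i}, \qquad A_i = 2\,L_i\,\mathrm{ESW}_i\,g(0)_i,$$

where $n_i$ is the number of sightings, $s_i$ the mean observed group
size, $L_i$ the segment length (km), $\mathrm{ESW}_i$ the effective
strip half-width (km) and $g(0)_i$ the trackline detection probability.
ESW and $g(0)$ are supplied per Beaufort sea state through a
`detection_table`; the bundled `detection_fixture()` carries *synthetic*
monotone values (detection degrades with wind), not published
coefficients — real analyses load their own table as CSV.

## The simulator

* **Environment** (`make_env_fields()`): daily 0.1° fields of SST, SSH,
  MLD and a static depth grid. SST is a deterministic latitudinal
  gradient (default 0.5 °C per degree, warm in the south) plus seeded
  smooth spatial noise; sdSST/sdSSH are the sample standard deviations
  over the 3 × 3 cell box centred on each cell. In ocean-model products
  the mixed-layer depth is defined by a 0.5 °C deviation from the
  surface temperature; here MLD is generated directly as a smooth
  positive field rather than derived from temperature profiles —
  profiles would add cost without touching any downstream code path. Heatwave days add a uniform anomaly (default
  +2 °C) *and* displace the isotherms poleward, so the anomaly is a
  lower bound on the per-cell SST difference. Two SSH sources are
  emulated: days from the "near-real-time" source are stored 0.035 m
  low and harmonized at covariate sampling, exercising the reference-
  level offset path.
* **Species truth** (`species_truth()`): an inhomogeneous Poisson group
  process. Log-intensity is a sum of named response primitives
  (monotone, unimodal, threshold); group sizes are lognormal, floored
  at one animal, with an optional latitudinal meanlog gradient.
  Optional per-year multipliers act on intensity and on group size; a
  year with intensity multiplier < 1 and size multiplier > 1 is a
  *concentration* year — fewer, larger groups, the regime in which
  occupancy falls while animal density rises.
* **Survey** (`simulate_survey()`): effort is discretized into 1-km
  steps along systematic east–west transects at ~18 km/hr; Beaufort
  evolves as a sticky first-order Markov chain over states 0–6 (states
  above 5 are produced deliberately so the downstream filter has work
  to do). Detected groups within the truncation distance $w$ arrive as
  a Poisson process with rate $\lambda \cdot 2\,\mathrm{ESW}\,g(0)$ per
  km; perpendicular distances follow a half-normal whose scale is
  solved so its integral to $w$ equals the tabulated ESW, plus a tail
  of beyond-truncation detections (to $1.5w$) so the 5.5-km truncation
  rule is exercised. Group sizes are recorded as the mean of
  `n_observers` noisy estimates, floored at 1; the magnitude of the
  observer noise is a free parameter (`group_noise_sd`, default 1
  animal) because no empirical value is available for it.

## Segmentation conventions

Continuous effort runs of length $L$ are split into
$k = \max(1, \operatorname{round}(L/5))$ equal-length segments, which
conserves total effort exactly and keeps the offset comparable across
segments. Modal Beaufort represents a segment, with ties resolved to
the *higher* (detection-conservative) state. Covariates are read from
the grid cell containing the segment midpoint on the segment's date —
nearest cell centre, no interpolation, matching the native 0.1°
resolution. A sighting is assigned to the segment containing its
along-track position (nearest midpoint on the same date when track
topology is unavailable); sightings beyond 5.5 km perpendicular are
discarded before assignment.

# The model families

## Density GAMs

Counts (individuals for whale-like single-response models, group
encounters for the delphinid two-stage form) are modeled with a
log-link Tweedie GAM with $\log A_i$ as offset, so the linear predictor
is a density. The Tweedie power is profiled by REML over the fixed grid
1.1–1.9 (step 0.1) — reproducible and robust where joint optimization
can wander — with a fallback to 1.3 when the profile is flat within
0.01 REML units. All smooths use shrinkage bases (`bs = "ts"`, basis
dimension 5 for univariate terms); bivariate interactions (lon–lat or
latitude × dynamic variable) enter as tensor products, at most one per
candidate model, with marginal basis dimension 3 (~10 coefficients
total). Backwards pruning (`prune_terms()`) repeatedly drops the least
significant term with approximate p > .05 and refits until every
retained term is significant; p-values are the Wald-type smooth-term
tests reported by the REML fit.

The group-size stage is Gaussian on $\log s_i$ over presence segments
with a lon–lat tensor smooth; response-scale predictions apply the
lognormal mean correction $\exp(\hat\mu + \hat\sigma^2/2)$. Whether the
original workflow applied this correction is not documented anywhere we
know of, so it is a switch (`bias_correct`, default on — the
statistically consistent choice for a mean). Two-stage density is the
product of the encounter-rate prediction (at 1 km² reference effective
area) and the predicted group size.

## Presence/absence models

The presence GAM is binomial/logit on segment occupancy with the same
shrinkage-plus-pruning machinery. The BRT uses gradient-boosted trees
with binomial deviance, tree complexity (interaction depth) 3, bag
fraction 0.6, and a learning rate halved from 0.05 until the 10-fold
cross-validation-optimal tree count reaches 1,000 (an error if the rate
underflows 1e-5 first). A uniform-random "screen" variable is offered
as a predictor in every run; only variables whose relative influence
strictly exceeds the screen's are retained, and the model is refitted
on the retained set. `select_best_brt()` fits four variable-combination
variants (dynamic+bathymetric, +lat, +lon, all) × 10 stochastic
iterations (bagging seed varies; folds are re-drawn per seed) and ranks
candidates by cross-validated deviance, with training AUC then TSS as
tie-breaks and the lowest seed index on exact ties. Cross-validated
deviance is primary because the remaining metrics are explanatory; the
choice is exposed in configuration.

# Prediction and uncertainty

Daily composites evaluate a fitted model cell-wise on one day's
covariates; the multiyear surface is their cell-wise mean. Lognormal
90% confidence surfaces use the distance-sampling convention
$C = \exp\!\big(z\sqrt{\ln(1+\mathrm{CV}^2)}\big)$, low = mean/C,
high = mean·C, with the per-cell CV computed from the temporal
variability of the daily surfaces. By default the CV is that of the
*mean* (SE/mean), so the interval is a genuine confidence interval for
the long-run cell mean with ~90% coverage; `cv = "daily"` gives the raw
temporal CV (sd/mean) for an interval describing day-to-day spread.
Variance is per cell, not pooled. Cell areas are cos-latitude weighted.
Surfaces are clipped to a study-area polygon (cell centres outside are
masked — predictions are never extrapolated off the modeled region) and
displayed in eight equal-numbered (quantile) bins.

# Evaluation battery

* **AUC** by the rank identity (ties count ½), equal to brute-force
  pairwise concordance.
* **TSS** = sensitivity + specificity − 1 at the **max-SSS** threshold,
  found by exhaustive scan over midpoints of consecutive sorted unique
  scores (ties → lowest threshold).
* **Stratified Spearman validation**: observed vs. predicted values
  across eight strata — four north–south latitude bands × an
  inshore/offshore split at the 2,000-m isobath. Observed stratum
  density is the Horvitz–Thompson-style ratio
  $\sum n_i s_i / \sum A_i$; observed suitability is the occupied
  fraction. The one-tailed p-value comes from complete enumeration of
  all $n!$ rank permutations for $n \le 9$ (40,320 at $n=8$,
  effectively instantaneous), a t approximation above.
* **Observed:predicted ratios**: study-area totals for density models;
  for suitability models the count of occupied segments over the sum of
  predicted probabilities — the natural calibration ratio, since no
  standard definition of an "observed suitability total" exists.
* **Novel-year cross-validation** (`novel_year_cv()`): every model
  family is re-fitted without the holdout year, predicts the holdout
  segments and environment, and reports holdout calibration plus a
  difference surface (holdout-average prediction minus training-average
  prediction). A leak check asserts holdout segments never reach
  training.

# What the simulations do and do not show

The generator reproduces the *statistical* structure the methods
assume: smooth dynamic covariates with a dominant latitudinal gradient,
Poisson group counts thinned by Beaufort-dependent detection, lognormal
group sizes, sea-state attrition of effort, and a warm-anomaly year
with poleward-displaced isotherms. It deliberately omits ocean-model
realism (fronts, eddies, advection), spatial autocorrelation of
sightings beyond what covariates induce, multi-species interaction and
observer heterogeneity. Passing tests therefore demonstrate that the
estimators and the comparison harness behave correctly under the
assumed data-generating process — not that any particular real species
follows that process.

The packaged validation scenarios use these problem sizes, chosen as
the smallest that leave the checked properties comfortably away from
their noise floors: ~5,000 segments for offset-calibration and
covariate-recovery checks (matching the scale at which the calibration
tolerance of 0.5% is meaningful); 100 seeded replicates for the BRT
screening null; and 20 replicates of the heatwave-holdout comparison.
The holdout scenario makes the warm year a *concentration* year
(intensity × 0.5, group size × 2.0, on top of a warm-affinity response
to a +2 °C anomaly): total animals increase and shift poleward while
occupancy falls — the regime in which a density model, which responds
to animal numbers, stays calibrated while presence/absence models,
blind to group size, misstate the change. This mirrors the documented
failure mode of suitability models during range contractions with
rising abundance.

# Numerical choices and degenerate inputs

* Tweedie profile tolerance 0.01 REML units; fallback power 1.3.
* Term pruning drops NA-p-value (fully shrunk) terms first.
* `segment_effort()` skips zero-length runs with a warning; an
  all-filtered segment set is a warning (empty result), not an error.
* `max_sss_threshold()` includes open-ended candidates beyond the score
  range, so degenerate score vectors still classify.
* Spearman p-values compare with a 1e-12 slack so exact-rational ties
  in the permutation null are counted on the correct side.
* `lognormal_ci()` returns the degenerate interval (0, 0) for
  zero-mean cells; probability surfaces are capped at 1 after the
  multiplicative high bound.
* Half-normal detection scale: when the tabulated ESW approaches the
  truncation distance the scale solver saturates (effectively uniform
  detection within the strip).

# Known limitations

* The BRT engine is gradient boosting with depth-limited trees; tree
  counts and influence decompositions are engine-specific, so only
  engine-independent properties (screening soundness, determinism,
  ranking) are asserted.
* Smooth-term p-values are approximate; the pruning loop's contract
  (every retained term significant at the threshold) is what is
  guaranteed, not agreement with any particular test statistic.
* Strata are latitude-band × isobath membership rules rather than
  GIS-exact polygons; study-area clipping does use true polygons.
* Gridded I/O is long-format CSV with CF-style column names rather than
  netCDF.
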