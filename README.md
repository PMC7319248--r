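# cetsdm

Tools for building and stress-testing species distribution models (SDMs)
from systematic shipboard line-transect surveys of cetaceans, in the
style of the multi-decade California Current monitoring programs. The
package compares the three model families in routine use for these
data — a **density GAM** (Tweedie counts with a log effective-area
offset, optionally two-stage with a lognormal group-size model), a
**presence/absence GAM** (binomial/logit), and a **presence/absence
boosted regression tree** (BRT) — and evaluates both their explanatory
power and their ability to predict a withheld, anomalously warm survey
year.

Because the real survey data and ocean-model fields cannot ship with a
package, `cetsdm` includes a first-class synthetic-data module: daily
0.1° environmental grids (SST and its 3×3-box standard deviation, SSH,
sdSSH, mixed-layer depth, bathymetry) with a latitudinal temperature
gradient and an optional marine-heatwave year, systematic transect
effort with a Markov Beaufort sea-state process, and species sightings
generated as an inhomogeneous Poisson group process thinned by
Beaufort-dependent detection. Every estimator in the package is tested
against this generator and against independent brute-force oracles.

## The model

Density on a ~5-km effort segment *i* follows the standard
line-transect identity

```
D_i = n_i * s_i / A_i,    A_i = 2 * L_i * ESW_i * g(0)_i
```

with `n_i` sightings, mean group size `s_i`, segment length `L_i`,
effective strip half-width `ESW_i` and trackline detection probability
`g(0)_i` (both functions of Beaufort state). Count models use
`log(A_i)` as an offset so the fitted surface is a density; smooths use
shrinkage bases with backwards pruning at p ≤ .05; the Tweedie power is
profiled over 1.1–1.9 by REML. BRTs use tree complexity 3, bag fraction
0.6, a learning rate tuned so the CV-optimal model keeps at least 1,000
trees, and a random-number screening variable that candidate predictors
must beat to be retained. Evaluation covers explained deviance, AUC,
TSS at the max-SSS threshold, observed:predicted calibration ratios,
and a Spearman rank test across eight geographic strata (four latitude
bands × an inshore/offshore split at the 2,000-m isobath) with an exact
one-tailed permutation p-value.

## Worked example

```r
library(cetsdm)

# a small three-season survey of a warm-affinity delphinid
cfg <- default_run_config(seed = 11)
out <- run_pipeline(cfg)
attr(out, "reports")$density
```

Output from this run:

```
Expl.Dev. 4.36%  AUC 0.610  TSS 0.178 (thr 0.152)  Obs:Pred 0.985
Stratified Spearman rho 0.810 (one-tailed p 0.0109, significant)
```

Reading this the way SDM summary tables are read: the density GAM
explains ~4% of segment-level deviance (typical for encounter data
dominated by sampling noise), discriminates occupied from unoccupied
segments modestly (AUC 0.61), its study-area prediction is calibrated
to within 2% (Obs:Pred 0.985), and its ranking of the effort-covered
geographic strata correlates strongly with the survey-derived ranking
(rho = 0.81, significant against the exact one-tailed permutation
null). The run directory also contains the segment table, fitted-model
JSON, BRT influence table and leaderboard, prediction surfaces, and a
manifest recording the seed.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `05_novel_year_cv.R`) at a larger problem size,
writing tables under `results/`: simulate the multiyear survey with a
heatwave holdout year, fit all three model families, build average and
90%-confidence density surfaces, run the explanatory battery, and
finish with novel-year cross-validation and difference surfaces.

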