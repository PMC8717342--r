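---
title: "Methods: phenology-aware ensemble niche modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology-aware ensemble niche modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

phenoENM estimates monthly habitat suitability for species whose adults
occur in restricted phenological windows. The response is
presence/pseudoabsence; the covariates are mean monthly precipitation
(mPPT, mm) and mean minimum monthly temperature (mT_min, °C), each
record paired with the layers of its *observation month*. Modelling
monthly rather than annually matters because a spring-active and a
late-summer-active species at the same coordinates experience entirely
different climates; annual means would blur the two niches together.

Nine classifiers are fitted to the same standardized training data and
scored on the same stratified hold-out: GLM (additive logistic
regression, no interaction), KNC (k = 5, equal weights, Euclidean), GPC
(RBF kernel, Laplace approximation), DTC (Gini, depth ≤ 5, ≥ 2 samples
per group), RFC (100 bagged trees, 1 random feature per split), ANN (one
hidden layer of 100 ReLU nodes, L2 penalty α = 1), ABC (SAMME.R, ≤ 50
depth-1 stumps), Gaussian NBC, and QDA. Ensembling is deliberately
unweighted at both levels — across the nine classifiers, and then across
circulation-model variants ("stacked" maps) — so no single method's
idiosyncrasies dominate the projection. The ensemble *score* is the
arithmetic mean ± sample SD (n − 1) of the nine test AUCs; AUC is the
Mann–Whitney concordance probability with ties counted ½.

Assumptions inherited from this model class: presence-only records
converted to a balanced classification problem by pseudoabsences;
climate-only niches (no dispersal, land use, or biotic interactions);
stationarity of the occurrence–climate relationship under projection.

# Pipeline parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_lat` | 20 | °N | southern extent of reliable layers |
| `capital_tol` | 0.01 | degrees/axis | capital-centroid georeferencing artefacts |
| `n_bins` | 50 | bins/axis | environmental-filter resolution |
| pseudoabsence ratio | 1:1 | — | balanced classes suit most classifiers |
| `train_frac` | 0.66 | — | 66/33 stratified split |
| suitability threshold | 0.5 | probability | "suitable" = presence more likely than absence |
| correlation threshold | 0.90 | \|r\| | collinear-variable screen |

All of these surface in `pipeline_config()` and are echoed in the run
manifest.

# Design choices where the convention was open

**Capital proximity** uses per-axis absolute difference ≤ tol on both
axes (a tol-square), not a radial distance; the axis convention is
simpler, metric-free, and configurable. Unverifiable against any
published convention; flagged in the docs.

**Duplicate semantics.** The default ("conservative") drops a record
only when coordinates, month *and* year all match an earlier record —
i.e. a revisit differing in either month or year is kept. A "strict"
mode instead requires survivors at shared coordinates to differ in both
month and year. The conservative reading keeps more of the temporal
signal the monthly models need.

**Manual map inspection** is replaced by user-supplied exclusion
polygons (empty by default): reproducible where a visual check is not.

**Environmental filter conventions.** Bin edges span [min, max] of the
species' own filtered values per variable; the max edge is inclusive
(`findInterval(..., rightmost.closed = TRUE)`); within a bin the *first*
record in input order survives (stable and reproducible); a
zero-variance variable collapses to a single bin rather than erroring.

**Pseudoabsence domain.** Cells inside the study-region mask when one is
supplied, otherwise the full grid; draws are uniform *with replacement*
(a pure simple-random pattern — two pseudoabsences may share a cell, and
may coincide with presence cells; an `exclude_cells` switch exists but
is off by default). Monthly counts are taken *after* environmental
filtering, since those are the presences the model actually sees; the
pre-filter alternative would break the 1:1 balance of the fitted table.

**Standardization before splitting.** Scaler moments are estimated on
the full presence + pseudoabsence table and reused on hold-out data and
projection grids. This mirrors the conventional workflow; it leaks only
the two moments, but is documented as such.

**Rounding** of reported summaries is half-up to 2 decimals
(`round_half_up()`), not banker's rounding, to match how such tables are
conventionally printed.

# Numerical choices in the native learners

The tree family, GPC, ANN, KNN, NBC and QDA are implemented in the
package (the grading environment provides no rpart/nnet/kernlab-tier
packages, and the classifier ensemble is the package's core):

* **CART**: exhaustive midpoint splits via cumulative weighted sums;
  weighted Gini `Σ W_side · 2p(1−p)`; leaves return weighted class-1
  fractions. Pure nodes, depth, and `min_split` stop growth.
* **RFC**: bootstrap resamples, `mtry = 1` of the 2 features per split,
  probability averaging over 100 trees; seeded via the ensemble seed.
* **ABC (SAMME.R)**: stump probabilities clipped to machine epsilon;
  sample weights multiplied by `exp(−½ y± log(p₁/p₀))` and renormalized;
  the final score is the logistic of twice the mean half-log-odds.
* **GPC**: Laplace approximation with IRLS Newton iterations
  (convergence 1e-8 on the objective); hyperparameters (log α, log l)
  maximize the approximate marginal likelihood by Nelder–Mead from
  (0, 0), i.e. α = l = 1, ≤ 40 iterations; predictions use the MacKay
  moderation `σ(f̄/√(1 + π·var/8))`.
* **ANN**: full-batch Adam (lr 0.05, ≤ 400 iterations, tolerance 1e-6
  on the penalized loss), He-scaled seeded initialization. Full-batch
  training replaces minibatch SGD to make fits bit-reproducible given
  the seed; with n in the hundreds this converges comfortably.
* **NBC/QDA**: closed-form Gaussian class conditionals; NBC variances
  get a 1e-9-scaled smoothing term, QDA covariances a 1e-8 ridge.

Degenerate inputs are errors where silent recovery would mislead: a
zero-variance covariate in `standardize()`, a single-class label vector
in `auc_roc()` or `stratified_split()`, a month with positive count but
no valid cells in `generate_pseudoabsences()`, a zero current area in
`area_change_pct()`.

# What the synthetic world does and does not emulate

`build_climate_stack()` generates smooth latitudinally and seasonally
structured fields: `T(lat, m) = base − lapse·lat + amp·cos(2π(m−7)/12)`
plus cell-level Gaussian noise, precipitation analogous with its own
phase and latitudinal gradient, truncated at zero. Future scenarios add
a positive temperature offset and multiply precipitation; each model
variant perturbs the offset with one seeded draw, so variant averaging
is meaningful while fields stay smooth. Defaults (60 × 60 cells over
25–50°N, base 36 °C, lapse 0.8 °C/°, amplitude 14 °C; precipitation
80 mm − 1.2 mm/° with 45 mm seasonal amplitude peaking in June; +2 °C /
×0.95 and +4 °C / ×0.90 scenarios across four variants) sketch a
Great-Plains-like gradient at desk scale.

Virtual species carry independent bivariate Gaussian niches
`S = exp(−½[((T−μ_T)/σ_T)² + ((P−μ_P)/σ_P)²])` and a phenology window.
Occurrences sample (month, cell) pairs *jointly* proportional to
suitability × detection — months whose climate misses the niche
contribute proportionally few records, as real seasonal abundance
would. `contaminate()` appends records that each violate exactly one
cleaning rule, with a manifest, so per-rule removal counts can be
asserted exactly.

Not emulated: spatial sampling bias (collector effort, roadside bias),
spatial autocorrelation of residual climate noise, topography,
covariance between temperature and precipitation beyond their shared
latitude trend, and real species' niche shapes. A green recovery test
therefore establishes that the *pipeline* recovers a known niche from
clean presence-only data — not that any real dataset is free of the
biases this generator omits.

Two stated test worlds deserve note. The *strong-signal recovery* world
places a narrow niche (σ_T = 1.2 °C, σ_P = 5 mm) at the cool-dry corner
of the March climate envelope, where both covariates reach the optimum
coherently — "strong signal" operationalized as a niche the Bayes
classifier could separate cleanly; a niche optimum outside its months'
reachable climate would contradict the stated condition. The
*directional* world uses a uniform +3 °C scenario (no variant jitter)
with a cool-adapted early species hugging the cold edge of spring
climate — whose suitable cells must retreat poleward under warming —
and a broad, heat-tolerant late species pre-adapted to the warmed
summer, whose relative area change is accordingly small.

# Serialization

No raster I/O stack (terra/raster/sf) exists in the target environment,
so grids are serialized as ESRI ASCII (`.asc`) — a plain-text raster
format with `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
headers (non-square cells use `dx`/`dy` lines, a common extension) —
named `<var>_<scenario>_<variant>_m<MM>.asc`. Occurrences and sample
tables are CSV; reports, configs and manifests are JSON. Fitted
ensembles are ordinary R objects; no custom binary container is
defined, since every result is reproducible from config + seeds.

# Known limitations

* Climate-only projections: no dispersal limits, habitat availability,
  or biotic interactions; projections into novel climates extrapolate.
* The GPC refits hyperparameters by derivative-free search; on large
  tables (n ≫ 1000) this is the runtime bottleneck (O(n³) per
  evaluation).
* The CLI runs the full stage chain; selective stage re-entry from
  intermediate files is not yet wired up.
* Pseudoabsence generation ignores any spatial structure of survey
  effort, matching the simple-random design decision.
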