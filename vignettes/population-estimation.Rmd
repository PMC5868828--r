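---
title: "Hierarchical range-wide population estimation: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical range-wide population estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carnipop)
```

# The estimation problem

A range-wide population size for a secretive carnivore cannot be counted
directly. What usually exists instead is (i) a heterogeneous compilation of
local camera-trap density estimates, (ii) an independent presence/absence
point set, and (iii) gridded environmental and anthropogenic covariates.
`carnipop` turns these into a total population estimate by modelling two
quantities separately and combining them:

* **potential density** — the density a cell could support given its
  environment, estimated from camera-trap studies (which are typically
  sited in little-disturbed areas, so their densities reflect habitat, not
  human suppression);
* **probability of occurrence** — whether the cell is actually occupied,
  estimated from presence/absence data that *do* include human-driven
  absences.

The core assumption is that these two processes are governed by different
mechanisms (productivity sets attainable density; occupancy responds to
both environment and people), so their product — density conditional on
occupancy — approximates realized density. This assumption is untestable
from the inputs themselves; it is what the simulation validation exercises
under a correctly specified generator.

# Pipeline stages and their assumptions

## Density harmonization

Non-spatial capture-recapture estimates (half mean-maximum-distance-moved
buffer, "½MMDM") systematically overestimate density relative to spatially
explicit capture-recapture (SCR). `fit_rescaling_regression()` fits OLS of
the SCR estimate on the ½MMDM estimate over studies reporting both (mean of
the maximum-likelihood and Bayesian SCR values where a study reports both
frameworks). `standardize_density_estimates()` then gives every study one
SCR-level value — its own SCR estimate where available, the regression
prediction of its ½MMDM value otherwise, zero for zero-capture studies —
and averages repeat studies at a site.

Two points were genuinely open and are decided here:

* *Rescale first, then average per site.* Averaging raw values across
  studies that used different methods would mix scales; rescaling first
  makes the site mean a mean of commensurable quantities.
* *Negative rescaled predictions are clamped to zero.* With a positive
  calibration intercept this never triggers; it is a guard for other data.

The packaged `jaguar_density_studies()` table is a **synthetic
reconstruction** (the original per-study compilation is not
redistributable): 117 studies over 80 sites with the published structure —
53 dual-method, 5 SCR-only, 59 non-spatial (8 zero-capture) — whose 53
pairs are calibrated so the regression reproduces the published line
(slope 0.54761, intercept 0.07391, R² 0.76, residual SE 1.06) exactly.

## Model selection

Both regressions use the same protocol:

1. **Collinearity screen** (`screen_collinearity()`): among candidate
   covariates, any pair with |Pearson r| > 0.7 loses the member less
   correlated (in absolute value) with the response, iterating from the
   strongest pair. Ties drop the later column, so the result is
   deterministic. A constant covariate is an error naming the column.
2. **All-subsets fits ranked by BIC** (`fit_all_subsets_linear()`,
   `fit_all_subsets_logistic()`): every non-empty covariate subset is
   fitted; `BIC = k ln n − 2 ln L̂`. For the linear model `k` counts the
   intercept, slopes, *and the residual variance* (k = p + 2) — the
   standard likelihood-based count, matching `stats::BIC`. The count is
   constant across subsets of the same data, so rankings are unaffected by
   the convention, but absolute BIC values from software using k = p + 1
   differ by a constant. Equal BIC ties (rare beyond degenerate data) are
   broken toward fewer covariates, then lexicographically. Singular
   subsets are skipped with a warning rather than failing the enumeration.
3. **Diagnostics**: squared semi-partial correlations
   (`semi_partial_r2()`, sr²ᵢ = (1 − R²) t²ᵢ / df_res, algebraically the
   R² drop when covariate *i* is removed — the suite checks this identity
   against refits), bootstrap coefficient bias and SE
   (`bootstrap_fit()`, resampling rows with replacement, default 10,000
   replicates, singular resamples redrawn and counted), Nagelkerke R²,
   rank-based AUC with ties counted one half, a 0.5-threshold
   classification table, and repeated stratified 75/25 cross-validation.

The cross-validation protocol deserves a note: a literal "10-fold" split
cannot have a 75/25 train/test ratio, so `cross_validate()` implements ten
independent random stratified 75/25 subsampling runs, reporting one AUC per
run — the reading consistent with "an AUC value for each run". Complete
separation in a logistic fit is flagged (and the model retained with a
warning), not treated as failure.

## Point preparation

* `thin_points()` enforces a 5-km minimum separation by a greedy scan in
  input order: a point is kept iff it is ≥ 5 km (haversine on a 6,371-km
  sphere) from every already-kept point. The greedy rule is one of several
  defensible thinning algorithms; a distance-to-centroid ordering is
  available via `order = "distance"`. Sub-metre geodesic accuracy is
  irrelevant at a 5-km rule, hence the spherical distance.
* `generate_pseudo_absences()` draws eligible cells uniformly without
  replacement and places absences at cell centres — covariates are
  cell-valued, so continuous-space placement would add no information.

## The hierarchical population model

For cell *i* and retained draw *j*:

\[ z_{ij} \sim \mathrm{Bern}(p_{ij}), \qquad
   d_{ij} \sim \mathrm{N}(\bar d_{ij}, \sigma^2_j) \text{ truncated at } 0,
   \qquad \hat d_{ij} = d_{ij} z_{ij} \cdot \text{cellArea}/100 . \]

Densities are per 100 km², so on a 10-km grid the area factor is exactly 1.
Totals are sums over cells per draw; the point estimate and 95% credible
interval are the mean and 2.5/97.5 percentiles over draws; per-cell mean
and SD surfaces are computed over the same retained draws.

**Sampler.** `sample_coefficient_posteriors()` is a single-chain sampler
written for exactly this model: conjugate Gibbs updates for the linear
model (coefficients given σ², then σ² given coefficients) and an adaptive
random-walk Metropolis step for the logistic coefficients (joint Normal
proposal, scale adapted during burn-in toward a 23.4% acceptance rate by a
Robbins–Monro recursion, then frozen so the retained chain is a valid
Metropolis sampler). Covariates are standardized to mean 0, SD 1; every
coefficient, including both intercepts, has a Normal prior with mean 0 and
precision 0.001 on that scale. Defaults: 100,000 iterations, burn-in 1,000,
thin 100 — 990 retained joint draws. An autocorrelation-based effective
sample size below 50 raises a warning, never an error.

Choices that the problem statement leaves open, and why they were made:

* *σ² prior*: inverse-gamma with shape = rate = 0.001, the conventional
  vague choice in JAGS-style hierarchical models; `fix_sigma2` bypasses
  sampling entirely (used by the conjugate-oracle tests).
* *Truncation of density draws*: `N(d̄, σ²)` has positive mass below zero
  wherever d̄ is small; draws are censored at zero before multiplication
  (so the per-cell expectation is `p·E[max(N(d̄,σ²),0)]`, which is the
  analytic oracle the tests use). `truncate = FALSE` restores the plain
  Normal draw for fidelity comparisons.
* *Occupancy and density are redrawn independently per cell per retained
  draw*, matching the generative statement `d̂ = d·z`.
* *Scenario pairing*: `run_scenarios()` computes all region masks in one
  pass over the same per-cell draws, so scenario totals are additive over
  disjoint regions and monotone over nested regions *exactly, per draw*.

## Grids

No raster package is required: grids are plain matrices in a
`covariate_grid` container with ESRI ASCII grid I/O (`read_ascii_grid()` /
`write_ascii_grid()`), block-mean aggregation to coarser cells
(`aggregate_grid()`, NA propagates), and containing-cell covariate
extraction (`extract_covariates_at_points()`) under a half-open
[x, x+w) × [y, y+h) convention — a boundary point belongs to the cell whose
lower-left region contains it. Human-density-style skewed layers can be
log-transformed at extraction as log10(x + 1); the offset admits zeros and
is configurable. Cell areas come from the stated equal-area cell size; the
package does no reprojection.

# The synthetic-landscape generator

`sim_config()` / `generate_landscape()` emulate the structure the estimator
assumes: `n_cells` cells (default study size 175,000, each representing
100 km²), six independent standard-normal continuous covariates (an
optional correlation matrix is accepted), one Bernoulli(0.5) binary
covariate, a density surface equal to the linear predictor plus
N(0, σ²) noise censored at zero, and occupancy drawn
Bernoulli(expit(logit)). `sample_observations()` takes simple random
samples without replacement of `floor(fraction · n_cells)` cells — 0.05%
for density and 2% for occurrence by default, i.e. 87 density cells and
3,500 occurrence cells at the default landscape size.

Default generating coefficients were fixed once, before any validation was
run, to produce realistic range-wide structure: densities centred near
2.5 per 100 km² with residual SD 1.37 (the residual scale of the empirical
density model), roughly 5–7% of cells censored at zero, and a mean
occupancy near 0.57 with strong covariate signal on a subset of covariates
(the rest intentionally null, exercising selection).

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: spatial autocorrelation of covariates or
residuals, covariate measurement error, non-linear responses, detection
error in the presence/absence labels, and the geographic clustering of real
camera-trap sites. The generator is a correctly specified world for the
estimator; validation demonstrates statistical correctness of the
machinery, not robustness to misspecification.

# Replicated validation

`run_validation_replicates()` repeats generate → sample → MCMC → estimate,
recording per replicate the true total, posterior mean, relative error
`100(estimate − truth)/truth` (signed values stored; summaries use absolute
values) and whether the 95% credible interval covers the truth. Failed
replicates are recorded and excluded with a count, never silently dropped.

The desk-scale study run by the test suite uses 20 replicates on
5,000-cell landscapes with MCMC shortened to 10,000 iterations (burn-in
500, thin 10). At 5,000 cells a 0.05% density fraction would leave 2
observations — fewer than the model's eight parameters, so nothing could
be estimated; the desk configuration therefore keeps the *empirical
density sample size* (87 studies, the binding data constraint of the real
analysis) and the 2% occurrence fraction (100 points). The suite requires
mean absolute relative error below 20% and CI coverage of at least 85%
under these conditions.

# Numerical notes and degenerate inputs

* OLS and logistic fits go through `stats::lm` / `stats::glm`; BIC is
  computed from the stated formula and agrees with `stats::BIC` to 1e-8 in
  the tests.
* The Gibbs coefficient update solves the conjugate Normal system by
  Cholesky factorization; the Metropolis chain is initialized at the
  maximum-likelihood logistic fit with its asymptotic covariance as
  proposal shape (identity fallback if singular).
* `logit()`/`expit()` are probability-space maps; the inverse identity
  holds to ~1e-9 for |g| ≤ 12 but degrades to ~1e-3 by |g| = 30 because
  expit(30) is within 1e-13 of 1 in double precision. Saturated logits are
  therefore compared on the probability scale, never the logit scale.
* Degenerate situations are contracts, not accidents: empty masks warn and
  return zero; a constant response centres slope posteriors at zero; a
  perfectly fitted bootstrap has exactly zero bias; p ≡ 0 gives a
  zero-width interval at zero; fraction-1 sampling returns all cells in
  index order.

# Known limitations

* The adjusted-density interpretation (potential density × occupancy)
  inherits the untestable independence assumption described above.
* Presence/absence data are taken at face value: no detection-probability
  correction is attempted.
* The MCMC runs a single chain by default, as in the estimation protocol
  it reimplements; the effective-sample-size warning is a heuristic, not a
  convergence proof.
* Grid handling assumes equal-area planar layers; geographic (lon/lat)
  rasters must be projected upstream.
* The packaged study table is a calibrated synthetic stand-in; analyses of
  the real compilation require the original per-study values.
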