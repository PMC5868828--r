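# carnipop

Range-wide population estimation for wide-ranging carnivores, built around
the jaguar (*Panthera onca*) analysis pipeline: harmonize heterogeneous
camera-trap density estimates, model potential density and probability of
occurrence from environmental and anthropogenic covariates, and combine the
two models hierarchically over a grid to estimate total population size with
credible intervals.

The package is aimed at quantitative ecologists who have (a) a compilation
of published density estimates of mixed methodology, (b) a presence/absence
point set, and (c) gridded covariates, and who want a reproducible,
simulation-validated total population estimate — together with every
intermediate product (rescaling regression, BIC model selection tables,
semi-partial correlations, bootstrap biases, AUC/cross-validation, posterior
draws, per-cell uncertainty surfaces).

## The model

**Density harmonization.** Non-spatial capture-recapture densities (half
mean-maximum-distance-moved buffer, ½MMDM) systematically exceed spatially
explicit capture-recapture (SCR) densities. Studies reporting both calibrate
an OLS regression `SCR = a + b·½MMDM` which rescales ½MMDM-only studies to
the SCR level; repeat studies at a site are averaged.

**Potential density.** Multiple linear regression of per-site SCR-level
density (per 100 km²) on candidate covariates, screened for collinearity
(|r| > 0.7 drops the member less correlated with the response), with
all-subsets fits ranked by BIC = k·ln n − 2·ln L̂. Covariate importance uses
squared semi-partial correlations, sr²ᵢ = (1 − R²)·t²ᵢ / df_res.

**Occurrence.** All-subsets logistic regression on thinned (≥ 5 km)
presence/absence points plus pseudo-absences, selected by BIC and summarized
by Nagelkerke R², AUC, and a 0.5-threshold classification table; logits
convert to probabilities by p(x) = e^g(x) / (1 + e^g(x)).

**Hierarchical population model.** For cell *i* and posterior draw *j*:

    z_ij ~ Bernoulli(p_ij)          p from the occurrence model
    d_ij ~ Normal(d̄_ij, σ²_j)      d̄ from the density model, truncated at 0
    d̂_ij = d_ij · z_ij · cellArea/100

Coefficient uncertainty enters through MCMC: a Gibbs sampler with conjugate
updates for the linear model (Normal priors with mean 0, precision 0.001 on
standardized covariates; vague inverse-gamma on σ²) and adaptive random-walk
Metropolis for the logistic coefficients. A single chain of 100,000
iterations with 1,000 burn-in, thinned by 100, retains 990 joint draws.
Summing d̂ over cells per draw yields the posterior of the total; the
2.5th–97.5th percentiles give the 95% credible interval.

**Validation.** A synthetic-landscape generator (175,000 cells by default,
six standard-normal plus one binary covariate, linear density with Normal
noise truncated at zero, logistic occupancy, 0.05% / 2% sub-sampling)
supports replicated end-to-end validation of the estimator with known truth.

## Worked example

```r
library(carnipop)

## 1. harmonize the packaged (synthetic reconstruction) study table
studies <- jaguar_density_studies()
fit <- fit_rescaling_regression(studies)
fit
#> Density rescaling regression (n = 53 paired studies)
#>   SCR = 0.07391 + 0.54761 * halfMMDM
#>   R^2 = 0.760, residual SE = 1.060 per 100 km^2
sites <- standardize_density_estimates(studies, fit)
nrow(sites)   # 80 sites, one harmonized density each

## 2. covariate importance from printed model summaries
round(semi_partial_r2(0.45, c(5.76, 4.40, 2.68, -3.27), 75), 2)
#> [1] 0.24 0.14 0.05 0.08

## 3. a synthetic landscape, end to end
cfg  <- sim_config(n_cells = 5000, density_sample_fraction = 87/5000,
                   occ_sample_fraction = 0.02, seed = 42)
land <- generate_landscape(cfg)      # true total: 7070.2 animals
obs  <- sample_observations(land, cfg)
draws <- sample_coefficient_posteriors(
  obs$density, obs$occurrence,
  density_covariates = names(land$covariates),
  occ_covariates    = names(land$covariates),
  settings = mcmc_settings(10000, 500, 10, seed = 1))
est <- estimate_population(draws, landscape_grid(land), seed = 2)
est
#> Population estimate over 5000 cells of 10 km
#>   mean 7066.2 animals, 95% CI 5857.5-8378.9 (950 draws)
```

The rescaling line, R² and residual SE are the calibration the per-site
table is built from; the semi-partial values rank covariates by their unique
contribution to explained variance; and the final block shows the
hierarchical estimator recovering a known synthetic total (7,070) within a
credible interval whose width reflects both coefficient and per-cell
stochastic uncertainty.

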