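# Shared builders for small in-code fixtures.

# linear-model data with a known generating subset
make_linear_data <- function(n, coefs, sigma = 1, n_null = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(coefs) - 1
  X <- matrix(rnorm(n * (p + n_null)), n)
  colnames(X) <- paste0("v", seq_len(p + n_null))
  y <- coefs[1] + X[, seq_len(p), drop = FALSE] %*% coefs[-1] +
    rnorm(n, 0, sigma)
  data.frame(y = drop(y), X)
}

# logistic-model data with known coefficients
make_logistic_data <- function(n, coefs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(coefs) - 1
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("v", seq_len(p))
  eta <- coefs[1] + drop(X %*% coefs[-1])
  data.frame(presence = rbinom(n, 1, plogis(eta)), X)
}

# a small grid with named constant or supplied layers
make_grid <- function(layers, cell_km = 10, xll = 0, yll = 0, masks = list()) {
  covariate_grid(layers, cell_km = cell_km, xll = xll, yll = yll,
                 masks = masks)
}

# posterior_draws object with every retained draw fixed at the given
# coefficients (standardization constants identity), for oracle checks of
# the per-cell Bernoulli x Normal stage in isolation
make_fixed_draws <- function(dens_coefs, sigma2, occ_coefs, covariates,
                             n_draws = 990) {
  p <- length(covariates)
  std <- list(mean = setNames(rep(0, p), covariates),
              sd = setNames(rep(1, p), covariates),
              covariates = covariates)
  structure(list(
    density_beta = matrix(rep(dens_coefs, each = n_draws), n_draws,
                          dimnames = list(NULL, c("(Intercept)", covariates))),
    sigma2 = rep(sigma2, n_draws),
    occ_beta = matrix(rep(occ_coefs, each = n_draws), n_draws,
                      dimnames = list(NULL, c("(Intercept)", covariates))),
    density_std = std, occ_std = std,
    settings = mcmc_settings(n_iter = n_draws, burn_in = 0, thin = 1),
    acceptance = NA_real_, ess_min = n_draws),
    class = "posterior_draws")
}

# mean of a Normal(mu, sd) truncated (censored) at zero: E[max(X, 0)]
truncnorm_mean <- function(mu, sd) {
  if (sd == 0) return(pmax(mu, 0))
  mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
}

# haversine distance (km) on a 6371-km sphere, written independently of the
# package for oracle checks
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  h <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}
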