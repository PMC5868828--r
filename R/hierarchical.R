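#' MCMC settings for the hierarchical population model
#'
#' Defaults match the estimation protocol used throughout the package: a
#' single chain of 100,000 iterations, the first 1,000 discarded as
#' burn-in, and every 100th of the remainder retained — exactly
#' `(100000 - 1000) / 100 = 990` joint coefficient draws.
#'
#' @param n_iter Total iterations (burn-in included).
#' @param burn_in Iterations discarded before retention starts.
#' @param thin Retain every `thin`-th post-burn-in iteration.
#' @param seed Optional integer seed for the whole sampler.
#' @param fix_sigma2 Optional fixed residual variance for the density
#'   model; when set, the variance is not sampled (used to compare against
#'   the conjugate closed form).
#' @param prior_precision Normal prior precision on every regression
#'   coefficient, standardized scale (default 0.001, i.e. variance 1000).
#' @param sigma2_prior Shape/rate of the vague inverse-gamma prior on the
#'   residual variance (default `c(0.001, 0.001)`).
#' @return List of class `mcmc_settings`; `n_retained` is precomputed.
#' @examples
#' mcmc_settings()$n_retained  # 990
#' @export
mcmc_settings <- function(n_iter = 100000L, burn_in = 1000L, thin = 100L,
                          seed = NULL, fix_sigma2 = NULL,
                          prior_precision = 0.001,
                          sigma2_prior = c(0.001, 0.001)) {
  .check(.is_count(n_iter) && .is_count(thin) &&
           is.numeric(burn_in) && burn_in >= 0 && burn_in == floor(burn_in),
         "iteration settings must be non-negative integers")
  .check(n_iter > burn_in, "`n_iter` must exceed `burn_in`")
  n_ret <- (n_iter - burn_in) %/% thin
  .check(n_ret >= 1, "settings retain no draws")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_retained = as.integer(n_ret),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 fix_sigma2 = fix_sigma2,
                 prior_precision = prior_precision,
                 sigma2_prior = sigma2_prior),
            class = "mcmc_settings")
}

# internal: standardize covariate columns to mean 0, sd 1; returns design
# matrix with intercept and the constants used
.standardize_design <- function(data, covariates) {
  X <- as.matrix(data[covariates])
  .check(is.numeric(X), "covariates must be numeric")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, sd)
  .check(all(sd_ > 0), "constant covariate(s): %s",
         paste(covariates[sd_ == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  list(X = cbind(`(Intercept)` = 1, Xs), mean = mu, sd = sd_,
       covariates = covariates)
}

# internal: Gibbs update of beta | sigma2 for the Normal linear model with
# N(0, 1/tau0) priors: posterior N(V X'y / s2, V), V = (X'X/s2 + tau0 I)^-1
.draw_beta_conjugate <- function(XtX, Xty, sigma2, tau0) {
  p <- ncol(XtX)
  A <- XtX / sigma2 + diag(tau0, p)
  R <- chol(A)                      # A = R'R
  m <- backsolve(R, backsolve(R, Xty / sigma2, transpose = TRUE))
  m + backsolve(R, rnorm(p))
}

# internal: log-likelihood + log-prior of logistic coefficients
.logpost_logistic <- function(beta, X, y, tau0) {
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll - tau0 / 2 * sum(beta^2)
}

#' Sample coefficient posteriors for the density and occurrence models
#'
#' Runs a single-chain MCMC over both top models jointly used by the
#' hierarchical population estimator:
#'
#' * the Normal linear **density** model, by Gibbs sampling with conjugate
#'   updates — coefficients given the residual variance, then the variance
#'   given the coefficients under a vague inverse-gamma prior;
#' * the logistic **occurrence** model, by adaptive random-walk Metropolis
#'   (joint proposal scaled during burn-in toward a 23.4% acceptance rate,
#'   then frozen).
#'
#' All covariates are standardized to mean 0, SD 1 before sampling, and all
#' coefficients carry Normal priors with mean 0 and precision 0.001 on that
#' scale. The standardization constants are stored so grid predictions can
#' be made with the training-scale coefficients.
#'
#' @param density_data Data frame of per-site densities and covariates.
#' @param occ_data Data frame of 0/1 presence records and covariates.
#' @param density_covariates,occ_covariates Covariate names of the two
#'   selected models.
#' @param density_response,occ_response Response column names (defaults
#'   `"density"`, `"presence"`).
#' @param settings An [mcmc_settings()] object.
#' @return Object of class `posterior_draws`: retained draws
#'   `density_beta` (matrix, standardized scale, intercept first),
#'   `sigma2`, `occ_beta`; the standardization constants `density_std`,
#'   `occ_std`; `settings`; the Metropolis `acceptance` rate; and
#'   `ess_min`, the smallest autocorrelation-adjusted effective sample size
#'   over all coefficients (a warning — not a failure — is raised when it
#'   falls below 50).
#' @export
sample_coefficient_posteriors <- function(density_data, occ_data,
                                          density_covariates,
                                          occ_covariates,
                                          density_response = "density",
                                          occ_response = "presence",
                                          settings = mcmc_settings()) {
  .check(inherits(settings, "mcmc_settings"),
         "`settings` must come from mcmc_settings()")
  .check(all(density_covariates %in% names(density_data)),
         "density covariates missing from `density_data`")
  .check(all(occ_covariates %in% names(occ_data)),
         "occurrence covariates missing from `occ_data`")
  if (!is.null(settings$seed)) set.seed(settings$seed)

  tau0 <- settings$prior_precision
  a0 <- settings$sigma2_prior[1]
  b0 <- settings$sigma2_prior[2]

  ## -- density design ------------------------------------------------------
  dstd <- .standardize_design(density_data, density_covariates)
  Xd <- dstd$X
  yd <- density_data[[density_response]]
  .check(is.numeric(yd) && !anyNA(yd), "density response must be numeric")
  nd <- length(yd)
  pd <- ncol(Xd)
  XtX <- crossprod(Xd)
  Xty <- crossprod(Xd, yd)
  beta_d <- qr.coef(qr(Xd), yd)          # init at OLS
  beta_d[is.na(beta_d)] <- 0
  sigma2 <- if (is.null(settings$fix_sigma2))
    max(mean((yd - Xd %*% beta_d)^2), 1e-8) else settings$fix_sigma2

  ## -- occurrence design ---------------------------------------------------
  ostd <- .standardize_design(occ_data, occ_covariates)
  Xo <- ostd$X
  yo <- occ_data[[occ_response]]
  .check(all(yo %in% c(0, 1)), "occurrence response must be 0/1")
  po <- ncol(Xo)
  glm0 <- suppressWarnings(glm.fit(Xo, yo, family = binomial()))
  beta_o <- coef(glm0)
  beta_o[is.na(beta_o) | abs(beta_o) > 15] <- 0
  # proposal covariance from the asymptotic vcov; fallback to identity
  W <- glm0$weights
  Sig <- tryCatch(solve(crossprod(Xo * sqrt(W)) + diag(tau0, po)),
                  error = function(e) diag(po))
  Lprop <- t(chol(Sig))
  log_s <- log(2.38 / sqrt(po))
  lp_o <- .logpost_logistic(beta_o, Xo, yo, tau0)

  ## -- iterate -------------------------------------------------------------
  n_ret <- settings$n_retained
  keep_d <- matrix(NA_real_, n_ret, pd,
                   dimnames = list(NULL, colnames(Xd)))
  keep_s2 <- numeric(n_ret)
  keep_o <- matrix(NA_real_, n_ret, po,
                   dimnames = list(NULL, colnames(Xo)))
  accept <- 0L
  k <- 0L
  for (it in seq_len(settings$n_iter)) {
    # density block: beta | sigma2, then sigma2 | beta
    beta_d <- .draw_beta_conjugate(XtX, Xty, sigma2, tau0)
    if (is.null(settings$fix_sigma2)) {
      sse <- sum((yd - Xd %*% beta_d)^2)
      sigma2 <- 1 / rgamma(1, a0 + nd / 2, b0 + sse / 2)
    }
    # occurrence block: adaptive random-walk Metropolis
    prop <- beta_o + exp(log_s) * drop(Lprop %*% rnorm(po))
    lp_prop <- .logpost_logistic(prop, Xo, yo, tau0)
    acc <- log(runif(1)) < lp_prop - lp_o
    if (acc) { beta_o <- prop; lp_o <- lp_prop }
    if (it <= settings$burn_in) {
      # Robbins-Monro adaptation of the proposal scale toward 0.234
      log_s <- log_s + it^-0.6 * ((if (acc) 1 else 0) - 0.234)
    } else {
      accept <- accept + as.integer(acc)
      off <- it - settings$burn_in
      if (off %% settings$thin == 0L && k < n_ret) {
        k <- k + 1L
        keep_d[k, ] <- beta_d
        keep_s2[k] <- sigma2
        keep_o[k, ] <- beta_o
      }
    }
  }
  acc_rate <- accept / (settings$n_iter - settings$burn_in)

  ess <- function(x) {
    v <- sd(x)
    if (!is.finite(v) || v == 0) return(length(x))
    a <- stats::acf(x, lag.max = min(50, length(x) - 1), plot = FALSE)$acf[-1]
    first_neg <- which(a < 0)[1]
    cutoff <- if (is.na(first_neg)) length(a) else max(1L, first_neg - 1L)
    length(x) / (1 + 2 * sum(a[seq_len(cutoff)], na.rm = TRUE))
  }
  ess_min <- min(apply(keep_d, 2, ess), apply(keep_o, 2, ess))
  if (ess_min < 50)
    warning(sprintf(
      "low effective sample size (%.0f) — consider more iterations", ess_min))

  structure(list(density_beta = keep_d, sigma2 = keep_s2,
                 occ_beta = keep_o,
                 density_std = dstd[c("mean", "sd", "covariates")],
                 occ_std = ostd[c("mean", "sd", "covariates")],
                 settings = settings,
                 acceptance = acc_rate,
                 ess_min = ess_min),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Posterior draws: %d retained (%d iterations, burn-in %d, thin %d)\n",
    s$n_retained, s$n_iter, s$burn_in, s$thin))
  cat(sprintf("  density coefficients: %d; occurrence coefficients: %d\n",
              ncol(x$density_beta), ncol(x$occ_beta)))
  cat(sprintf("  Metropolis acceptance %.2f; min ESS %.0f\n",
              x$acceptance, x$ess_min))
  invisible(x)
}

#' Back-transform standardized coefficients to the original scale
#'
#' @param draws A [sample_coefficient_posteriors()] result.
#' @param which `"density"` or `"occurrence"`.
#' @return Matrix of retained draws on the original covariate scale
#'   (intercept first).
#' @export
coefficients_original_scale <- function(draws,
                                        which = c("density", "occurrence")) {
  which <- match.arg(which)
  b <- if (which == "density") draws$density_beta else draws$occ_beta
  std <- if (which == "density") draws$density_std else draws$occ_std
  slopes <- sweep(b[, -1, drop = FALSE], 2, std$sd, "/")
  intercept <- b[, 1] - slopes %*% std$mean
  cbind(`(Intercept)` = drop(intercept), slopes)
}

# internal: standardized design matrix over grid cells for one model
.grid_design <- function(grid, std) {
  miss <- setdiff(std$covariates, names(grid$layers))
  .check(length(miss) == 0, "grid lacks covariate layer(s): %s",
         paste(miss, collapse = ", "))
  X <- vapply(std$covariates,
              function(v) as.vector(grid$layers[[v]]),
              numeric(length(grid$layers[[1]])))
  X <- sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
  cbind(1, X)
}

# internal: one pass over retained draws computing per-cell adjusted
# density and totals for each mask; cells with missing covariates excluded
.population_pass <- function(draws, grid, masks, truncate = TRUE,
                             seed = NULL) {
  .check(inherits(draws, "posterior_draws"),
         "`draws` must come from sample_coefficient_posteriors()")
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  d <- dim(grid$layers[[1]])
  for (m in masks)
    .check(identical(dim(m), d), "mask shape does not match the grid")
  if (!is.null(seed)) set.seed(seed)
  Xd <- .grid_design(grid, draws$density_std)
  Xo <- .grid_design(grid, draws$occ_std)
  ok <- complete.cases(Xd) & complete.cases(Xo)
  n_cells <- sum(ok)
  area_factor <- grid$cell_km^2 / 100   # density is per 100 km^2
  R <- nrow(draws$density_beta)
  mask_idx <- lapply(masks, function(m) which(as.vector(m)[ok]))
  totals <- matrix(0, R, length(masks))
  cell_sum <- numeric(n_cells)
  cell_sum2 <- numeric(n_cells)
  Xd_ok <- Xd[ok, , drop = FALSE]
  Xo_ok <- Xo[ok, , drop = FALSE]
  for (j in seq_len(R)) {
    p <- expit(drop(Xo_ok %*% draws$occ_beta[j, ]))
    z <- rbinom(n_cells, 1L, p)
    dbar <- drop(Xd_ok %*% draws$density_beta[j, ])
    dd <- rnorm(n_cells, dbar, sqrt(draws$sigma2[j]))
    if (truncate) dd <- pmax(dd, 0)
    dhat <- dd * z * area_factor
    cell_sum <- cell_sum + dhat
    cell_sum2 <- cell_sum2 + dhat^2
    for (m in seq_along(masks)) totals[j, m] <- sum(dhat[mask_idx[[m]]])
  }
  mean_grid <- matrix(NA_real_, d[1], d[2])
  sd_grid <- matrix(NA_real_, d[1], d[2])
  mean_grid[ok] <- cell_sum / R
  sd_grid[ok] <- sqrt(pmax(cell_sum2 / R - (cell_sum / R)^2, 0) * R / (R - 1))
  list(totals = totals, mean_grid = mean_grid, sd_grid = sd_grid,
       ok = ok, mask_idx = mask_idx, area_factor = area_factor)
}

# internal: summarize a totals vector into a population_estimate
.make_estimate <- function(totals, pass, grid, mask, region_table) {
  structure(list(totals = totals,
                 mean = mean(totals),
                 ci = unname(quantile(totals, c(0.025, 0.975))),
                 per_cell_mean = pass$mean_grid,
                 per_cell_sd = pass$sd_grid,
                 region_table = region_table,
                 n_cells = if (is.null(mask)) sum(pass$ok)
                           else sum(as.vector(mask)[pass$ok]),
                 cell_km = grid$cell_km),
            class = "population_estimate")
}

#' Hierarchical population estimate over a grid
#'
#' For every retained coefficient draw and every grid cell: the occurrence
#' probability is the expit of the occurrence linear predictor and occupancy
#' `z` is a Bernoulli draw; density is a Normal draw around the density
#' linear predictor with the draw's residual variance, truncated at zero;
#' the cell's adjusted abundance is `density * z * cellArea / 100` (density
#' is per 100 km^2). Summing cells gives one total per draw; the mean and
#' the 2.5/97.5 percentiles over draws are the point estimate and 95%
#' credible interval. Per-cell posterior mean and SD grids are computed
#' over the same retained draws.
#'
#' @param draws A [sample_coefficient_posteriors()] result.
#' @param grid A [covariate_grid()] supplying both models' covariates (on
#'   the original, unstandardized scale; standardization constants from the
#'   training data are applied internally).
#' @param mask Optional logical matrix (or name of a grid mask) restricting
#'   the total to a region.
#' @param truncate Truncate negative density draws at zero (default
#'   `TRUE`); `FALSE` reproduces the untruncated Normal draw for fidelity
#'   comparisons.
#' @param seed Optional integer seed for the per-cell draws.
#' @return Object of class `population_estimate` with `totals` (one per
#'   retained draw), `mean`, `ci`, `per_cell_mean`, `per_cell_sd`,
#'   `n_cells`.
#' @export
estimate_population <- function(draws, grid, mask = NULL, truncate = TRUE,
                                seed = NULL) {
  m <- .resolve_mask(grid, mask)
  if (!any(m)) warning("mask selects no cells; estimate is zero")
  pass <- .population_pass(draws, grid, list(m), truncate = truncate,
                           seed = seed)
  .make_estimate(pass$totals[, 1], pass, grid, m, region_table = NULL)
}

# internal: mask argument -> logical matrix
.resolve_mask <- function(grid, mask) {
  d <- dim(grid$layers[[1]])
  if (is.null(mask)) return(matrix(TRUE, d[1], d[2]))
  if (is.character(mask)) {
    .check(mask %in% names(grid$masks), "mask `%s` not found in grid", mask)
    return(grid$masks[[mask]])
  }
  .check(is.logical(mask) && identical(dim(mask), d),
         "`mask` must be a logical matrix matching the grid")
  mask
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate over %d cells of %g km\n",
              x$n_cells, x$cell_km))
  cat(sprintf("  mean %.1f animals, 95%% CI %.1f-%.1f (%d draws)\n",
              x$mean, x$ci[1], x$ci[2], length(x$totals)))
  if (!is.null(x$region_table)) print(x$region_table, digits = 4)
  invisible(x)
}

#' Population estimates for several region scenarios from shared draws
#'
#' Computes [estimate_population()] restricted to each scenario mask in a
#' single pass over the retained draws, so every scenario sees the *same*
#' per-cell occupancy and density draws and scenario contrasts are paired:
#' disjoint regions add exactly per draw, and nested regions are ordered
#' per draw.
#'
#' @param draws A [sample_coefficient_posteriors()] result.
#' @param grid A [covariate_grid()].
#' @param scenario_masks Named list of logical matrices (or names of grid
#'   masks).
#' @param truncate,seed As in [estimate_population()].
#' @return Named list of `population_estimate` objects plus a `summary`
#'   data frame (region, cells, area in km^2, mean, CI bounds, mean density
#'   per 100 km^2).
#' @export
run_scenarios <- function(draws, grid, scenario_masks, truncate = TRUE,
                          seed = NULL) {
  .check(is.list(scenario_masks) && length(scenario_masks) >= 1 &&
           !is.null(names(scenario_masks)),
         "`scenario_masks` must be a named list")
  masks <- lapply(scenario_masks, .resolve_mask, grid = grid)
  empty <- !vapply(masks, any, logical(1))
  if (any(empty))
    warning(sprintf("empty scenario mask(s): %s; estimate is zero",
                    paste(names(masks)[empty], collapse = ", ")))
  pass <- .population_pass(draws, grid, masks, truncate = truncate,
                           seed = seed)
  ests <- lapply(seq_along(masks), function(m)
    .make_estimate(pass$totals[, m], pass, grid, masks[[m]], NULL))
  names(ests) <- names(masks)
  cell_area <- grid$cell_km^2
  summary <- data.frame(
    region = names(masks),
    n_cells = vapply(seq_along(masks),
                     function(m) length(pass$mask_idx[[m]]), 0L),
    stringsAsFactors = FALSE)
  summary$area_km2 <- summary$n_cells * cell_area
  summary$mean <- vapply(ests, function(e) e$mean, 0)
  summary$ci_low <- vapply(ests, function(e) e$ci[1], 0)
  summary$ci_high <- vapply(ests, function(e) e$ci[2], 0)
  summary$mean_density_100km2 <- ifelse(summary$area_km2 > 0,
                                        100 * summary$mean / summary$area_km2,
                                        0)
  ests$summary <- summary
  ests
}
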