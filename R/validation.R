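#' Replicated simulation validation of the hierarchical estimator
#'
#' Repeats the whole pipeline end to end on synthetic landscapes: for each
#' replicate a new landscape is generated from `config`, the configured
#' fractions of cells are sampled into density and occurrence observation
#' sets, the joint coefficient posterior is sampled by MCMC, and the
#' hierarchical model is evaluated over the full landscape. The replicate
#' records the true total, the posterior mean, the relative error
#' `100 * (estimate - truth) / truth` and whether the 95% credible interval
#' covers the truth. A replicate whose MCMC fails (e.g. a single-class
#' occurrence sample) is recorded as missing and excluded from summaries,
#' with a count.
#'
#' @param config A [sim_config()]; `config$seed` is ignored — per-replicate
#'   seeds are derived from `seed`.
#' @param n_replicates Number of replicates (default 100).
#' @param settings [mcmc_settings()] for each replicate's sampler.
#' @param seed Integer base seed; replicate `r` uses `seed + 10 * r` and
#'   two offsets of it, so replicates are independent and the whole run is
#'   reproducible.
#' @return Object of class `validation_result`: `replicates` (data frame
#'   with per-replicate truth, estimate, CI, relative error, coverage
#'   flag), `mae` (mean absolute relative error, %), `range_abs_error`
#'   (min/max absolute relative error), `coverage` (proportion of CIs
#'   covering truth), `n_failed`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cells = 2000, density_sample_fraction = 0.02,
#'                   occ_sample_fraction = 0.05)
#' res <- run_validation_replicates(cfg, n_replicates = 3,
#'   settings = mcmc_settings(2000, 200, 20), seed = 1)
#' res$mae
#' }
#' @export
run_validation_replicates <- function(config, n_replicates = 100L,
                                      settings = mcmc_settings(),
                                      seed = 1L) {
  .check(inherits(config, "sim_config"), "`config` must come from sim_config()")
  .check(.is_count(n_replicates), "`n_replicates` must be a positive integer")
  covs <- .cov_names(config)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    base <- as.integer(seed) + 10L * r
    cfg_r <- config
    cfg_r$seed <- base
    row <- tryCatch({
      land <- generate_landscape(cfg_r)
      obs <- sample_observations(land, cfg_r)
      set_r <- settings
      set_r$seed <- base + 2L
      draws <- suppressWarnings(sample_coefficient_posteriors(
        obs$density, obs$occurrence,
        density_covariates = covs, occ_covariates = covs,
        settings = set_r))
      grid <- landscape_grid(land)
      est <- estimate_population(draws, grid, seed = base + 3L)
      data.frame(replicate = r,
                 true_total = land$true_total,
                 estimate = est$mean,
                 ci_low = est$ci[1], ci_high = est$ci[2],
                 rel_error = 100 * (est$mean - land$true_total) /
                   land$true_total,
                 covered = est$ci[1] <= land$true_total &
                   land$true_total <= est$ci[2],
                 failed = FALSE)
    }, error = function(e) {
      data.frame(replicate = r, true_total = NA_real_, estimate = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 rel_error = NA_real_, covered = NA, failed = TRUE)
    })
    reps[[r]] <- row
  }
  tab <- do.call(rbind, reps)
  ok <- !tab$failed
  structure(list(replicates = tab,
                 mae = if (any(ok)) mean(abs(tab$rel_error[ok])) else NA_real_,
                 range_abs_error = if (any(ok)) range(abs(tab$rel_error[ok]))
                                   else c(NA_real_, NA_real_),
                 coverage = if (any(ok)) mean(tab$covered[ok]) else NA_real_,
                 n_failed = sum(!ok)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  n_ok <- sum(!x$replicates$failed)
  cat(sprintf("Simulation validation: %d replicates (%d failed)\n",
              nrow(x$replicates), x$n_failed))
  cat(sprintf("  mean absolute relative error: %.2f%% (range %.2f-%.2f%%)\n",
              x$mae, x$range_abs_error[1], x$range_abs_error[2]))
  cat(sprintf("  95%% CI coverage of truth: %.0f%% of %d replicates\n",
              100 * x$coverage, n_ok))
  invisible(x)
}

#' Wrap a synthetic landscape's covariates as a covariate grid
#'
#' Lays the landscape's cells out as a 1 x n grid of 10-km cells (100 km^2
#' each, so a density per 100 km^2 is the expected count per cell), which
#' is all the hierarchical estimator needs — it has no spatial structure
#' beyond the per-cell covariates.
#'
#' @param landscape A [generate_landscape()] result.
#' @return A [covariate_grid()] with one layer per covariate.
#' @export
landscape_grid <- function(landscape) {
  .check(inherits(landscape, "synthetic_landscape"),
         "`landscape` must come from generate_landscape()")
  n <- nrow(landscape$covariates)
  layers <- lapply(landscape$covariates, function(v) matrix(v, nrow = 1))
  covariate_grid(layers, cell_km = 10)
}
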