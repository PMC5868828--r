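#' Configuration for a synthetic landscape
#'
#' Bundles the generating parameters of a virtual landscape: cell count,
#' covariate structure, the true density and occupancy coefficient vectors,
#' residual noise, and the fractions of cells sub-sampled into the density
#' and occurrence observation sets. One cell represents 100 km^2, so a
#' density expressed per 100 km^2 is also the expected number of animals in
#' a cell; on a 10 km grid the area factor is exactly 1.
#'
#' Defaults describe the validation landscape used throughout the package:
#' 175,000 cells, six independent standard-normal continuous covariates plus
#' one Bernoulli(0.5) binary covariate, a linear density surface with Normal
#' residual noise truncated at zero, logistic occupancy, and sub-sampling of
#' 0.05% of cells for density and 2% for occurrence.
#'
#' @param n_cells Positive integer, number of landscape cells.
#' @param n_cov_continuous Integer, number of continuous covariates
#'   (standard normal; default 6).
#' @param include_binary_cov Logical, include one Bernoulli(0.5) binary
#'   covariate (default `TRUE`).
#' @param density_coefs Numeric vector of length `1 + n_covariates`
#'   (intercept first) for the density linear predictor, on the per-100-km^2
#'   scale.
#' @param occ_coefs Numeric vector of the same length for the occupancy
#'   logit.
#' @param sigma Non-negative residual SD of density around its linear
#'   predictor (per 100 km^2).
#' @param density_sample_fraction,occ_sample_fraction Fractions in (0, 1] of
#'   cells sampled into the density and occurrence observation sets.
#' @param cov_cor Optional correlation matrix for the continuous covariates
#'   (default: mutually independent).
#' @param seed Integer seed; all generation under a fixed seed is
#'   bit-reproducible.
#' @return An object of class `sim_config` (a list of the above, with
#'   `n_cov` = total covariate count).
#' @seealso [generate_landscape()], [sample_observations()]
#' @examples
#' cfg <- sim_config(n_cells = 1000, seed = 1)
#' cfg$n_cov
#' @export
sim_config <- function(n_cells,
                       n_cov_continuous = 6L,
                       include_binary_cov = TRUE,
                       density_coefs = NULL,
                       occ_coefs = NULL,
                       sigma = 1.37,
                       density_sample_fraction = 0.0005,
                       occ_sample_fraction = 0.02,
                       cov_cor = NULL,
                       seed = NULL) {
  .check(.is_count(n_cells), "`n_cells` must be a positive integer")
  .check(is.numeric(n_cov_continuous) && n_cov_continuous >= 0 &&
           n_cov_continuous == floor(n_cov_continuous),
         "`n_cov_continuous` must be a non-negative integer")
  .check(.is_flag(include_binary_cov), "`include_binary_cov` must be TRUE/FALSE")
  .check(is.numeric(sigma) && length(sigma) == 1L && sigma >= 0,
         "`sigma` must be a non-negative scalar")
  for (f in c(density_sample_fraction, occ_sample_fraction))
    .check(is.numeric(f) && length(f) == 1L && f > 0 && f <= 1,
           "sampling fractions must lie in (0, 1]")
  n_cov <- as.integer(n_cov_continuous) + as.integer(include_binary_cov)
  .check(n_cov >= 1L, "at least one covariate is required")

  # default generating coefficients: moderate effects on four continuous
  # covariates and the binary one, densities on the 0-9 per 100 km^2 scale
  # seen in range-wide camera-trap compilations
  if (is.null(density_coefs))
    density_coefs <- .default_coefs(n_cov_continuous, include_binary_cov,
                                    intercept = 2.5,
                                    slopes = c(0.8, 0.5, 0.3, 0.2),
                                    binary_coef = -0.5)
  if (is.null(occ_coefs))
    occ_coefs <- .default_coefs(n_cov_continuous, include_binary_cov,
                                intercept = 0.75,
                                slopes = c(0.9, -0.6, 0.5),
                                binary_coef = -0.7)
  .check(length(density_coefs) == n_cov + 1L,
         "`density_coefs` must have length %d (intercept + covariates)",
         n_cov + 1L)
  .check(length(occ_coefs) == n_cov + 1L,
         "`occ_coefs` must have length %d (intercept + covariates)",
         n_cov + 1L)
  if (!is.null(cov_cor)) {
    .check(is.matrix(cov_cor) &&
             all(dim(cov_cor) == n_cov_continuous) &&
             isTRUE(all.equal(cov_cor, t(cov_cor))) &&
             all(abs(diag(cov_cor) - 1) < 1e-12),
           "`cov_cor` must be a %d x %d correlation matrix", n_cov_continuous,
           n_cov_continuous)
  }
  structure(
    list(n_cells = as.integer(n_cells),
         n_cov_continuous = as.integer(n_cov_continuous),
         include_binary_cov = include_binary_cov,
         n_cov = n_cov,
         density_coefs = as.numeric(density_coefs),
         occ_coefs = as.numeric(occ_coefs),
         sigma = sigma,
         density_sample_fraction = density_sample_fraction,
         occ_sample_fraction = occ_sample_fraction,
         cov_cor = cov_cor,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

.default_coefs <- function(n_cont, has_binary, intercept, slopes,
                           binary_coef = 0) {
  s <- rep(0, n_cont)
  k <- min(n_cont, length(slopes))
  s[seq_len(k)] <- slopes[seq_len(k)]
  c(intercept, s, if (has_binary) binary_coef)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic landscape configuration\n")
  cat(sprintf("  cells: %d (1 cell = 100 km^2)\n", x$n_cells))
  cat(sprintf("  covariates: %d continuous%s\n", x$n_cov_continuous,
              if (x$include_binary_cov) " + 1 binary" else ""))
  cat(sprintf("  density coefs: %s  (sigma = %.3g)\n",
              paste(signif(x$density_coefs, 3), collapse = ", "), x$sigma))
  cat(sprintf("  occupancy coefs: %s\n",
              paste(signif(x$occ_coefs, 3), collapse = ", ")))
  cat(sprintf("  sampling fractions: density %.4g%%, occurrence %.4g%%\n",
              100 * x$density_sample_fraction, 100 * x$occ_sample_fraction))
  invisible(x)
}

# internal: covariate names for a config
.cov_names <- function(config) {
  nm <- if (config$n_cov_continuous > 0)
    paste0("x", seq_len(config$n_cov_continuous)) else character()
  if (config$include_binary_cov) nm <- c(nm, "bin")
  nm
}

#' Generate a synthetic landscape
#'
#' Draws per-cell covariates (continuous standard normal, optionally
#' correlated; binary Bernoulli(0.5)), a true density surface equal to the
#' linear predictor plus Normal(0, `sigma`) noise truncated at zero, and a
#' true occupancy indicator drawn Bernoulli(expit(occupancy logit)). The
#' landscape's true total population is the sum of density times occupancy
#' over cells (one cell = 100 km^2, so density per 100 km^2 is animals per
#' cell).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_landscape`: a list with
#'   `covariates` (data frame, one row per cell), `true_density`,
#'   `true_occupancy`, `true_total` and the generating `config`.
#' @examples
#' land <- generate_landscape(sim_config(n_cells = 500, seed = 7))
#' land$true_total
#' @export
generate_landscape <- function(config) {
  .check(inherits(config, "sim_config"), "`config` must come from sim_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  p <- config$n_cov_continuous
  Z <- matrix(rnorm(n * p), n, p)
  if (!is.null(config$cov_cor) && p > 1)
    Z <- Z %*% chol(config$cov_cor)
  X <- Z
  if (config$include_binary_cov)
    X <- cbind(X, rbinom(n, 1L, 0.5))
  colnames(X) <- .cov_names(config)
  Xd <- cbind(1, X)
  mu <- drop(Xd %*% config$density_coefs)
  true_density <- pmax(mu + rnorm(n, 0, config$sigma), 0)
  p_occ <- expit(drop(Xd %*% config$occ_coefs))
  true_occupancy <- rbinom(n, 1L, p_occ)
  structure(
    list(covariates = as.data.frame(X),
         true_density = true_density,
         true_occupancy = true_occupancy,
         true_total = sum(true_density * true_occupancy),
         config = config),
    class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("Synthetic landscape: %d cells, %d covariates\n",
              x$config$n_cells, x$config$n_cov))
  cat(sprintf("  mean true density: %.3f per 100 km^2\n", mean(x$true_density)))
  cat(sprintf("  occupancy rate: %.3f\n", mean(x$true_occupancy)))
  cat(sprintf("  true total population: %.1f\n", x$true_total))
  invisible(x)
}

#' Sub-sample observations from a synthetic landscape
#'
#' Simple random sampling of cells without replacement, at the configured
#' fractions (sample sizes are `floor(fraction * n_cells)`). The density
#' table records the realized (noisy, truncated) density of each sampled
#' cell; the occurrence table records the true 0/1 occupancy. These play the
#' role of the camera-trap study table and the presence/absence point set.
#'
#' @param landscape A [generate_landscape()] result.
#' @param config The same [sim_config()] the landscape was generated from.
#'   Sampling is seeded from `config$seed` so a fixed seed gives identical
#'   samples on every call.
#' @return A list with `density` (data frame: `cell`, covariates, `density`)
#'   and `occurrence` (data frame: `cell`, covariates, `presence`).
#' @examples
#' cfg <- sim_config(n_cells = 1000, density_sample_fraction = 0.05, seed = 2)
#' land <- generate_landscape(cfg)
#' obs <- sample_observations(land, cfg)
#' nrow(obs$density)  # floor(0.05 * 1000) = 50
#' @export
sample_observations <- function(landscape, config = landscape$config) {
  .check(inherits(landscape, "synthetic_landscape"),
         "`landscape` must come from generate_landscape()")
  n <- config$n_cells
  .check(n == nrow(landscape$covariates),
         "`config` does not match the landscape (cell counts differ)")
  n_d <- floor(config$density_sample_fraction * n)
  n_o <- floor(config$occ_sample_fraction * n)
  .check(n_d >= 1, "density sampling fraction %.3g yields an empty sample",
         config$density_sample_fraction)
  .check(n_o >= 1, "occurrence sampling fraction %.3g yields an empty sample",
         config$occ_sample_fraction)
  # offset from the landscape seed so sampling does not replay the same
  # stream that generated the cells
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  idx_d <- if (n_d == n) seq_len(n) else sort(sample.int(n, n_d))
  idx_o <- if (n_o == n) seq_len(n) else sort(sample.int(n, n_o))
  list(
    density = cbind(data.frame(cell = idx_d),
                    landscape$covariates[idx_d, , drop = FALSE],
                    data.frame(density = landscape$true_density[idx_d],
                               row.names = NULL)),
    occurrence = cbind(data.frame(cell = idx_o),
                       landscape$covariates[idx_o, , drop = FALSE],
                       data.frame(presence = landscape$true_occupancy[idx_o],
                                  row.names = NULL)))
}

#' Simulate paired non-spatial / SCR density estimates
#'
#' Fixture generator for the density-harmonization regression: half-MMDM
#' densities are drawn uniformly over `mmdm_range` and the paired SCR
#' estimate is `intercept + slope * mmdm + Normal(0, noise_sd)`. With
#' `noise_sd = 0` the pairs lie exactly on the specified line, so refitting
#' recovers the slope and intercept to machine tolerance.
#'
#' @param n Number of paired studies (at least 3).
#' @param slope,intercept Generating line relating SCR to half-MMDM density.
#' @param noise_sd Non-negative SD of Normal noise around the line.
#' @param mmdm_range Length-2 range for the uniform half-MMDM draw
#'   (default 0 to 18.3 per 100 km^2).
#' @param seed Optional integer seed.
#' @return Data frame with `study_id`, `d_mmdm`, `d_scr`.
#' @examples
#' pairs <- generate_paired_density_studies(50, 0.55, 0.07, 0.5, seed = 1)
#' coef(lm(d_scr ~ d_mmdm, pairs))
#' @export
generate_paired_density_studies <- function(n, slope, intercept, noise_sd,
                                            mmdm_range = c(0, 18.3),
                                            seed = NULL) {
  .check(.is_count(n) && n >= 3, "`n` must be an integer >= 3")
  .check(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d_mmdm <- runif(n, mmdm_range[1], mmdm_range[2])
  d_scr <- intercept + slope * d_mmdm + rnorm(n, 0, noise_sd)
  data.frame(study_id = sprintf("sim%03d", seq_len(n)),
             d_mmdm = d_mmdm, d_scr = d_scr)
}

#' Write a synthetic landscape and its observations as CSV
#'
#' Writes `landscape.csv` (covariates plus true density/occupancy),
#' `density_obs.csv`, `occurrence_obs.csv` and a flat `config.txt`
#' (key = value lines, seed included) into `dir`.
#'
#' @param landscape A [generate_landscape()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_landscape_csv <- function(landscape, dir) {
  .check(inherits(landscape, "synthetic_landscape"),
         "`landscape` must come from generate_landscape()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- landscape$config
  obs <- sample_observations(landscape, cfg)
  land_df <- cbind(landscape$covariates,
                   true_density = landscape$true_density,
                   true_occupancy = landscape$true_occupancy)
  paths <- file.path(dir, c("landscape.csv", "density_obs.csv",
                            "occurrence_obs.csv", "config.txt"))
  write.csv(land_df, paths[1], row.names = FALSE)
  write.csv(obs$density, paths[2], row.names = FALSE)
  write.csv(obs$occurrence, paths[3], row.names = FALSE)
  keys <- c(n_cells = cfg$n_cells,
            n_cov_continuous = cfg$n_cov_continuous,
            include_binary_cov = cfg$include_binary_cov,
            sigma = cfg$sigma,
            density_sample_fraction = cfg$density_sample_fraction,
            occ_sample_fraction = cfg$occ_sample_fraction,
            density_coefs = paste(cfg$density_coefs, collapse = ","),
            occ_coefs = paste(cfg$occ_coefs, collapse = ","),
            seed = if (is.null(cfg$seed)) "NA" else cfg$seed)
  writeLines(paste(names(keys), unname(keys), sep = " = "), paths[4])
  invisible(paths)
}
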