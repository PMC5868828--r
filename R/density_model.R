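#' Collinearity screen for candidate covariates
#'
#' Pairwise Pearson correlations among candidate covariates are examined;
#' whenever a pair exceeds the threshold in absolute value, the member less
#' correlated (in absolute value) with the response is removed. The scan
#' iterates from the strongest offending pair until every retained pair has
#' `|r| <= threshold`.
#'
#' @param data Data frame containing `response` and all `candidates`.
#' @param candidates Character vector of candidate covariate columns.
#' @param response Name of the response column.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return List with `retained` (covariate names), `dropped` (data frame:
#'   variable, partner, r, reason), and `cor_matrix` (candidate
#'   correlations).
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50))
#' d$b <- d$a  # duplicate covariate
#' d$c <- rnorm(50)
#' screen_collinearity(d, c("a", "b", "c"), "y")$retained
#' @export
screen_collinearity <- function(data, candidates, response, threshold = 0.7) {
  .check(length(candidates) >= 2, "need at least 2 candidate covariates")
  .check(all(candidates %in% names(data)), "candidates missing from `data`")
  .check(response %in% names(data), "response column `%s` missing", response)
  sds <- vapply(data[candidates], sd, numeric(1))
  .check(all(sds > 0), "constant covariate(s): %s",
         paste(candidates[sds == 0], collapse = ", "))
  cm <- cor(data[candidates])
  ry <- abs(cor(data[candidates], data[[response]])[, 1])
  retained <- candidates
  dropped <- data.frame(variable = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    sub <- abs(cm[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (all(sub <= threshold)) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- retained[ij[1]]; b <- retained[ij[2]]
    # drop the member less correlated with the response; ties drop the
    # later column for determinism
    victim <- if (ry[a] < ry[b]) a else if (ry[b] < ry[a]) b
              else retained[max(ij)]
    partner <- setdiff(c(a, b), victim)
    dropped <- rbind(dropped,
                     data.frame(variable = victim, partner = partner,
                                r = cm[a, b], stringsAsFactors = FALSE))
    retained <- setdiff(retained, victim)
  }
  list(retained = retained, dropped = dropped, cor_matrix = cm)
}

#' Squared semi-partial (part) correlation from model summaries
#'
#' The unique contribution of covariate *i* to a multiple regression's
#' explained variance, computed from printed model output as
#' `(1 - R^2) * t_i^2 / df_res`, where `R^2` is the full model's coefficient
#' of determination, `t_i` the covariate's t statistic and `df_res` the
#' residual degrees of freedom. Algebraically this equals the drop in R^2
#' when covariate *i* is removed from the model.
#'
#' @param r2 Coefficient of determination of the full model, in \[0, 1\].
#' @param t_i t statistic(s) of the covariate(s); vectorized.
#' @param df_res Residual degrees of freedom (positive integer).
#' @return Numeric vector of squared semi-partial correlations.
#' @examples
#' semi_partial_r2(0.45, c(5.76, 4.40, 2.68, -3.27), 75)
#' @export
semi_partial_r2 <- function(r2, t_i, df_res) {
  .check(is.numeric(r2) && length(r2) == 1L && r2 >= 0 && r2 <= 1,
         "`r2` must be a scalar in [0, 1]")
  .check(is.numeric(df_res) && length(df_res) == 1L && df_res >= 1,
         "`df_res` must be a positive integer")
  (1 - r2) * t_i^2 / df_res
}

# internal: gaussian log-likelihood of an OLS fit, BIC with k = p + 2
# (intercept + slopes + residual variance)
.ols_bic <- function(rss, n, p) {
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 2
  c(loglik = ll, bic = k * log(n) - 2 * ll)
}

# internal: summarize one OLS subset fit into a linear_model_fit
.linear_fit <- function(data, covs, response) {
  fml <- stats::reformulate(covs, response = response)
  m <- lm(fml, data = data)
  if (anyNA(coef(m))) return(NULL)   # singular design
  s <- summary(m)
  n <- nrow(data)
  p <- length(covs)
  ct <- s$coefficients
  b <- .ols_bic(sum(residuals(m)^2), n, p)
  sr2 <- semi_partial_r2(s$r.squared, ct[-1, "t value"], m$df.residual)
  structure(
    list(covariates = covs,
         coefficients = data.frame(
           term = rownames(ct),
           estimate = ct[, "Estimate"],
           se = ct[, "Std. Error"],
           t = ct[, "t value"],
           p_value = ct[, "Pr(>|t|)"],
           sr2 = c(NA_real_, sr2),
           row.names = NULL),
         r2 = s$r.squared,
         see = s$sigma,
         loglik = unname(b["loglik"]),
         bic = unname(b["bic"]),
         df_res = m$df.residual,
         n = n,
         fitted = unname(fitted(m)),
         std_residuals = unname(stats::rstandard(m)),
         model = m),
    class = "linear_model_fit")
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("Linear density model: %s\n", paste(x$covariates, collapse = " + ")))
  cat(sprintf("  n = %d, R^2 = %.3f, SEE = %.3f, BIC = %.2f, df_res = %d\n",
              x$n, x$r2, x$see, x$bic, x$df_res))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' All-subsets linear regression ranked by BIC
#'
#' Fits ordinary least squares for every non-empty subset of the candidate
#' covariates and ranks the models by the Bayesian Information Criterion
#' `BIC = k * ln(n) - 2 * lnL`, where `k` counts the intercept, the slopes
#' and the residual variance. Reports Delta-BIC relative to the best model
#' and BIC weights `exp(-Delta/2)` normalized over all fitted subsets. Ties
#' in BIC are broken in favour of fewer covariates, then lexicographically.
#'
#' @param data Data frame with the response and candidate covariates.
#' @param candidates Character vector of candidate covariate columns.
#' @param response Name of the response column.
#' @param top Number of models to keep in the ranking table (default 10;
#'   the best fit itself is always returned in full).
#' @return List of class `subset_ranking` with `ranking` (data frame:
#'   `model`, `n_covariates`, `bic`, `delta_bic`, `weight`, `r2`,
#'   `all_significant`), `best` (a `linear_model_fit`), `n_models`, and
#'   `skipped` (count of singular subsets skipped with a warning).
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60))
#' d$y <- 1 + 2 * d$x1 + rnorm(60)
#' fit_all_subsets_linear(d, c("x1", "x2", "x3"), "y")$best$covariates
#' @export
fit_all_subsets_linear <- function(data, candidates, response, top = 10L) {
  .check(length(candidates) >= 1, "need at least 1 candidate covariate")
  .check(all(candidates %in% names(data)), "candidates missing from `data`")
  n <- nrow(data)
  .check(n > length(candidates) + 1,
         "need n > number of candidates + 1 (n = %d)", n)
  subsets <- .all_subsets(candidates)
  fits <- vector("list", length(subsets))
  skipped <- 0L
  for (i in seq_along(subsets)) {
    f <- .linear_fit(data, subsets[[i]], response)
    if (is.null(f)) {
      warning(sprintf("singular design for subset {%s}; skipped",
                      paste(subsets[[i]], collapse = ", ")))
      skipped <- skipped + 1L
    }
    fits[[i]] <- f
  }
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  ranking <- data.frame(
    model = vapply(fits, function(f) paste(f$covariates, collapse = " + "), ""),
    n_covariates = vapply(fits, function(f) length(f$covariates), 0L),
    bic = vapply(fits, function(f) f$bic, 0),
    r2 = vapply(fits, function(f) f$r2, 0),
    all_significant = vapply(fits, function(f)
      all(f$coefficients$p_value[-1] < 0.05), NA),
    stringsAsFactors = FALSE)
  ord <- order(ranking$bic, ranking$n_covariates, ranking$model)
  ranking <- ranking[ord, , drop = FALSE]
  fits <- fits[ord]
  ranking$delta_bic <- ranking$bic - ranking$bic[1]
  w <- exp(-ranking$delta_bic / 2)
  ranking$weight <- w / sum(w)
  rownames(ranking) <- NULL
  ranking <- ranking[, c("model", "n_covariates", "bic", "delta_bic",
                         "weight", "r2", "all_significant")]
  structure(list(ranking = head(ranking, top),
                 best = fits[[1]],
                 n_models = nrow(ranking),
                 skipped = skipped),
            class = "subset_ranking")
}

# internal: all non-empty subsets, smallest first
.all_subsets <- function(candidates) {
  .check(length(candidates) <= 20,
         "all-subsets enumeration capped at 20 candidates (got %d)",
         length(candidates))
  out <- list()
  for (k in seq_along(candidates))
    out <- c(out, combn(candidates, k, simplify = FALSE))
  out
}

#' @export
print.subset_ranking <- function(x, ...) {
  cat(sprintf("All-subsets model selection: %d models fitted%s\n",
              x$n_models,
              if (x$skipped > 0) sprintf(" (%d singular, skipped)", x$skipped)
              else ""))
  print(x$ranking, digits = 4)
  invisible(x)
}

#' Bootstrap bias and SE of regression coefficients
#'
#' Resamples rows of the data with replacement, refits the selected model on
#' each replicate, and reports per-coefficient bias (mean bootstrap estimate
#' minus original estimate) and bootstrap SE (SD over replicates).
#' Degenerate (singular) resamples are redrawn and counted.
#'
#' @param data Data frame used for the original fit.
#' @param covariates Covariates of the selected model.
#' @param response Response column name.
#' @param reps Number of bootstrap replicates (default 10,000).
#' @param seed Optional integer seed.
#' @param family `"gaussian"` for OLS (default) or `"binomial"` for a
#'   logistic model.
#' @return Data frame with `term`, `estimate`, `bias`, `se_boot`; attributes
#'   `reps` and `redrawn` (count of redrawn singular resamples).
#' @examples
#' d <- data.frame(x = rnorm(40)); d$y <- 1 + d$x + rnorm(40)
#' bootstrap_fit(d, "x", "y", reps = 200, seed = 1)
#' @export
bootstrap_fit <- function(data, covariates, response, reps = 10000L,
                          seed = NULL, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  .check(.is_count(reps), "`reps` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  X <- model.matrix(stats::reformulate(covariates), data = data)
  y <- data[[response]]
  n <- nrow(X)
  p <- ncol(X)
  fit0 <- if (family == "gaussian") qr.coef(qr(X), y)
          else coef(glm.fit(X, y, family = binomial()))
  .check(!anyNA(fit0), "selected model is singular on the full data")
  boot <- matrix(NA_real_, reps, p)
  redrawn <- 0L
  r <- 1L
  while (r <= reps) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- if (family == "gaussian") {
      q <- qr(X[idx, , drop = FALSE])
      if (q$rank < p) NULL else qr.coef(q, y[idx])
    } else {
      f <- suppressWarnings(try(glm.fit(X[idx, , drop = FALSE], y[idx],
                                        family = binomial()), silent = TRUE))
      if (inherits(f, "try-error") || !f$converged) NULL else coef(f)
    }
    if (is.null(cf) || anyNA(cf)) { redrawn <- redrawn + 1L; next }
    boot[r, ] <- cf
    r <- r + 1L
  }
  out <- data.frame(term = colnames(X),
                    estimate = unname(fit0),
                    bias = colMeans(boot) - unname(fit0),
                    se_boot = apply(boot, 2, sd),
                    row.names = NULL)
  attr(out, "reps") <- reps
  attr(out, "redrawn") <- redrawn
  out
}

#' Write a structured model report
#'
#' Serializes a fitted model's coefficient table and fit statistics to a
#' JSON file for archival alongside grid outputs.
#'
#' @param fit A `linear_model_fit` or `logistic_model_fit`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_report <- function(fit, path) {
  .check(inherits(fit, c("linear_model_fit", "logistic_model_fit")),
         "`fit` must be a linear or logistic model fit")
  .check(requireNamespace("jsonlite", quietly = TRUE),
         "the jsonlite package is required to write model reports")
  keep <- setdiff(names(fit), c("model", "fitted", "std_residuals"))
  jsonlite::write_json(fit[keep], path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Predict a potential-density surface over a covariate grid
#'
#' Applies a fitted linear density model cell-by-cell over a
#' [covariate_grid()], returning the linear predictor with negative values
#' clamped to zero (densities are non-negative). Cells with any missing
#' covariate propagate to missing.
#'
#' @param fit A `linear_model_fit`, or a named numeric coefficient vector
#'   whose first element is the intercept and remaining names match grid
#'   layers.
#' @param grid A [covariate_grid()] supplying every selected covariate as a
#'   layer.
#' @param clamp Clamp negative predictions at 0 (default `TRUE`); the
#'   hierarchical population model uses the unclamped predictor and handles
#'   negativity through its own truncation.
#' @return Matrix of predicted densities (per 100 km^2), same shape as the
#'   grid layers.
#' @export
predict_density_grid <- function(fit, grid, clamp = TRUE) {
  coefs <- .fit_coefs(fit)
  pred <- .grid_linpred(coefs, grid)
  if (clamp) pred[!is.na(pred) & pred < 0] <- 0
  pred
}

# internal: extract named coefficients (intercept first) from a fit object
.fit_coefs <- function(fit) {
  if (inherits(fit, "linear_model_fit") || inherits(fit, "logistic_model_fit")) {
    setNames(fit$coefficients$estimate, fit$coefficients$term)
  } else if (is.numeric(fit) && !is.null(names(fit))) {
    fit
  } else stop("`fit` must be a model fit or a named coefficient vector",
              call. = FALSE)
}

# internal: linear predictor over grid layers; names(coefs)[1] is intercept
.grid_linpred <- function(coefs, grid) {
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  covs <- names(coefs)[-1]
  miss <- setdiff(covs, names(grid$layers))
  .check(length(miss) == 0, "grid lacks covariate layer(s): %s",
         paste(miss, collapse = ", "))
  pred <- matrix(coefs[1], nrow(grid$layers[[1]]), ncol(grid$layers[[1]]))
  for (v in covs) pred <- pred + coefs[v] * grid$layers[[v]]
  pred
}
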