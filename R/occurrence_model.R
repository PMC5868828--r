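#' Spatial thinning of presence/absence points
#'
#' Reduces spatial autocorrelation by keeping at most one point per
#' neighbourhood: scanning points in input order, a point is kept only if
#' its great-circle distance to every already-kept point is at least
#' `min_dist_km`. Distances are haversine on a 6,371-km sphere.
#'
#' @param points Data frame with `longitude` and `latitude` in decimal
#'   degrees (WGS84).
#' @param min_dist_km Minimum separation in kilometres (default 5).
#' @param order `"input"` (default) scans in file order; `"distance"` scans
#'   points sorted by distance to the centroid, an alternative deterministic
#'   ordering.
#' @return The thinned subset of `points` (rows in original order).
#' @examples
#' pts <- data.frame(longitude = c(0, 0, 1), latitude = c(0, 0.001, 0))
#' nrow(thin_points(pts, 5))  # the two near-coincident points collapse
#' @export
thin_points <- function(points, min_dist_km = 5,
                        order = c("input", "distance")) {
  order <- match.arg(order)
  .check(all(c("longitude", "latitude") %in% names(points)),
         "`points` needs longitude/latitude columns")
  .check(all(points$latitude >= -90 & points$latitude <= 90),
         "latitude outside [-90, 90]")
  n <- nrow(points)
  if (n == 0) return(points)
  idx <- seq_len(n)
  if (order == "distance") {
    ctr <- c(mean(points$longitude), mean(points$latitude))
    d0 <- geosphere::distHaversine(
      as.matrix(points[, c("longitude", "latitude")]), ctr, r = 6371000)
    idx <- idx[base::order(d0)]
  }
  xy <- as.matrix(points[, c("longitude", "latitude")])
  kept <- integer(0)
  for (i in idx) {
    if (length(kept) == 0) { kept <- i; next }
    d <- geosphere::distHaversine(xy[kept, , drop = FALSE], xy[i, ],
                                  r = 6371000) / 1000
    if (all(d >= min_dist_km)) kept <- c(kept, i)
  }
  points[sort(kept), , drop = FALSE]
}

#' Random pseudo-absence points on a masked grid
#'
#' Samples `n` eligible cells uniformly without replacement and places an
#' absence point at each cell centre. Used to balance presence-heavy point
#' sets by generating background absences within a buffer outside the
#' species' current range.
#'
#' @param grid A [covariate_grid()].
#' @param mask Name of a logical mask in `grid$masks`, or a logical matrix
#'   of the grid's shape, marking eligible cells.
#' @param n Number of pseudo-absences (default 1,000).
#' @param seed Optional integer seed.
#' @return Data frame with cell-centre `x`, `y` (grid coordinates, km),
#'   `cell` (linear index), `presence = 0` and `source = "pseudo-absence"`.
#' @export
generate_pseudo_absences <- function(grid, mask, n = 1000L, seed = NULL) {
  .check(inherits(grid, "covariate_grid"), "`grid` must be a covariate_grid")
  m <- if (is.character(mask)) {
    .check(mask %in% names(grid$masks), "mask `%s` not found in grid", mask)
    grid$masks[[mask]]
  } else mask
  .check(is.logical(m) && all(dim(m) == dim(grid$layers[[1]])),
         "`mask` must be a logical matrix matching the grid shape")
  eligible <- which(m)
  .check(length(eligible) >= n,
         "only %d eligible cells for %d pseudo-absences", length(eligible), n)
  if (!is.null(seed)) set.seed(seed)
  cells <- if (length(eligible) == n) eligible
           else sort(sample(eligible, n))
  ctr <- cell_centers(grid, cells)
  data.frame(x = ctr$x, y = ctr$y, cell = cells,
             presence = 0L, source = "pseudo-absence",
             stringsAsFactors = FALSE)
}

#' Nagelkerke's pseudo R-squared
#'
#' Rescaled likelihood-ratio R^2 for binary-response models:
#' `(1 - exp(2 (l0 - l1) / n)) / (1 - exp(2 l0 / n))` with `l0` the
#' intercept-only log-likelihood and `l1` the model log-likelihood. Equals 0
#' when the model adds nothing and 1 for a perfect fit.
#'
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param loglik_model Log-likelihood of the fitted model (`>= loglik_null`).
#' @param n Number of observations.
#' @return Scalar in \[0, 1\].
#' @examples
#' nagelkerke_r2(-10, -10, 20)  # 0
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  .check(is.numeric(n) && length(n) == 1L && n > 0, "`n` must be positive")
  .check(loglik_model >= loglik_null - 1e-8,
         "`loglik_model` must be >= `loglik_null`")
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  cox_snell / (1 - exp(2 * loglik_null / n))
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half — the
#' Mann-Whitney statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric prediction scores (any monotone scale).
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  .check(length(scores) == length(labels), "lengths differ")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  .check(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal: one logistic fit summarized into a logistic_model_fit
.logistic_fit <- function(data, covs, response) {
  fml <- stats::reformulate(covs, response = response)
  m <- suppressWarnings(glm(fml, data = data, family = binomial()))
  if (anyNA(coef(m))) return(NULL)
  s <- summary(m)
  n <- nrow(data)
  ct <- s$coefficients
  ll <- as.numeric(logLik(m))
  m0 <- glm(stats::reformulate("1", response = response), data = data,
            family = binomial())
  ll0 <- as.numeric(logLik(m0))
  probs <- unname(fitted(m))
  y <- data[[response]]
  pred_cls <- as.integer(probs > 0.5)
  separated <- any(abs(ct[, "Estimate"]) > 15) ||
    all(probs > 0.999 | probs < 0.001)
  structure(
    list(covariates = covs,
         coefficients = data.frame(
           term = rownames(ct),
           estimate = ct[, "Estimate"],
           se = ct[, "Std. Error"],
           z = ct[, "z value"],
           p_value = ct[, "Pr(>|z|)"],
           odds_ratio = exp(ct[, "Estimate"]),
           row.names = NULL),
         loglik = ll,
         loglik_null = ll0,
         bic = (length(covs) + 1) * log(n) - 2 * ll,
         nagelkerke_r2 = nagelkerke_r2(ll0, ll, n),
         auc = auc_roc(probs, y),
         sensitivity = sum(pred_cls == 1 & y == 1) / sum(y == 1),
         specificity = sum(pred_cls == 0 & y == 0) / sum(y == 0),
         n = n,
         separated = separated,
         model = m),
    class = "logistic_model_fit")
}

#' @export
print.logistic_model_fit <- function(x, ...) {
  cat(sprintf("Logistic occurrence model: %s\n",
              paste(x$covariates, collapse = " + ")))
  cat(sprintf(
    "  n = %d, Nagelkerke R^2 = %.3f, AUC = %.3f, BIC = %.2f\n",
    x$n, x$nagelkerke_r2, x$auc, x$bic))
  cat(sprintf("  sensitivity = %.2f, specificity = %.2f (threshold 0.5)\n",
              x$sensitivity, x$specificity))
  if (x$separated) cat("  warning: possible complete separation\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' All-subsets logistic regression ranked by BIC
#'
#' Maximum-likelihood logistic fits for every non-empty subset of the
#' candidates, ranked by `BIC = k * ln(n) - 2 * lnL` (k = intercept +
#' slopes). The best model is returned in full with Nagelkerke R^2, AUC,
#' the 0.5-threshold classification table (sensitivity/specificity) and
#' odds ratios `exp(coefficient)`. Complete separation is flagged with a
#' warning but the model is retained.
#'
#' @inheritParams fit_all_subsets_linear
#' @param response Name of the 0/1 response column (default `"presence"`).
#' @return List of class `subset_ranking_logistic` with `ranking`
#'   (`model`, `n_covariates`, `bic`, `delta_bic`, `weight`,
#'   `nagelkerke_r2`, `auc`), `best` (a `logistic_model_fit`), `n_models`,
#'   `skipped`.
#' @export
fit_all_subsets_logistic <- function(data, candidates, response = "presence",
                                     top = 10L) {
  .check(length(candidates) >= 1, "need at least 1 candidate covariate")
  .check(all(candidates %in% names(data)), "candidates missing from `data`")
  y <- data[[response]]
  .check(all(y %in% c(0, 1)), "response must be 0/1")
  .check(any(y == 0) && any(y == 1), "both classes must be present")
  subsets <- .all_subsets(candidates)
  fits <- vector("list", length(subsets))
  skipped <- 0L
  for (i in seq_along(subsets)) {
    f <- .logistic_fit(data, subsets[[i]], response)
    if (is.null(f)) {
      warning(sprintf("singular design for subset {%s}; skipped",
                      paste(subsets[[i]], collapse = ", ")))
      skipped <- skipped + 1L
    }
    fits[[i]] <- f
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ranking <- data.frame(
    model = vapply(fits, function(f) paste(f$covariates, collapse = " + "), ""),
    n_covariates = vapply(fits, function(f) length(f$covariates), 0L),
    bic = vapply(fits, function(f) f$bic, 0),
    nagelkerke_r2 = vapply(fits, function(f) f$nagelkerke_r2, 0),
    auc = vapply(fits, function(f) f$auc, 0),
    stringsAsFactors = FALSE)
  ord <- order(ranking$bic, ranking$n_covariates, ranking$model)
  ranking <- ranking[ord, , drop = FALSE]
  fits <- fits[ord]
  ranking$delta_bic <- ranking$bic - ranking$bic[1]
  w <- exp(-ranking$delta_bic / 2)
  ranking$weight <- w / sum(w)
  rownames(ranking) <- NULL
  ranking <- ranking[, c("model", "n_covariates", "bic", "delta_bic",
                         "weight", "nagelkerke_r2", "auc")]
  best <- fits[[1]]
  if (best$separated)
    warning("best model shows signs of complete separation; retained")
  structure(list(ranking = head(ranking, top),
                 best = best,
                 n_models = nrow(ranking),
                 skipped = skipped),
            class = c("subset_ranking_logistic", "subset_ranking"))
}

#' ROC curve points
#'
#' Sensitivity and specificity at every distinct score threshold, suitable
#' for CSV export or plotting. The first row (threshold `-Inf`) classifies
#' everything positive; the last (`Inf`) everything negative.
#'
#' @inheritParams auc_roc
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(as.numeric(labels)))
  .check(any(labels == 1) && any(labels == 0), "both classes must be present")
  th <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  data.frame(
    threshold = th,
    sensitivity = vapply(th, function(t) sum(scores >= t & labels == 1) / n1,
                         0),
    specificity = vapply(th, function(t) sum(scores < t & labels == 0) / n0,
                         0))
}

#' Repeated random-split cross-validation of the occurrence model
#'
#' Runs `n_runs` independent stratified 75/25 train/holdout splits (the
#' split is stratified by class so both presences and absences appear in
#' every holdout), refits the selected logistic model on each training set,
#' and scores the holdout by AUC. A split whose holdout lacks a class is
#' redrawn and counted.
#'
#' @param data Data frame with response and covariates.
#' @param covariates Covariates of the selected model.
#' @param response Name of the 0/1 response column.
#' @param n_runs Number of random splits (default 10).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Optional integer seed.
#' @return List with `auc` (per-run vector), `mean`, `range`, `redrawn`.
#' @export
cross_validate <- function(data, covariates, response = "presence",
                           n_runs = 10L, train_frac = 0.75, seed = NULL) {
  .check(.is_count(n_runs), "`n_runs` must be a positive integer")
  .check(train_frac > 0 && train_frac < 1, "`train_frac` must be in (0, 1)")
  y <- data[[response]]
  .check(all(y %in% c(0, 1)) && any(y == 0) && any(y == 1),
         "response must be 0/1 with both classes present")
  if (!is.null(seed)) set.seed(seed)
  fml <- stats::reformulate(covariates, response = response)
  i1 <- which(y == 1); i0 <- which(y == 0)
  .check(length(i1) >= 4 && length(i0) >= 4,
         "too few points per class for a stratified split")
  aucs <- numeric(n_runs)
  redrawn <- 0L
  run <- 1L
  while (run <= n_runs) {
    tr <- c(sample(i1, round(train_frac * length(i1))),
            sample(i0, round(train_frac * length(i0))))
    ho <- setdiff(seq_along(y), tr)
    if (!any(y[ho] == 1) || !any(y[ho] == 0)) { redrawn <- redrawn + 1L; next }
    m <- suppressWarnings(glm(fml, data = data[tr, , drop = FALSE],
                              family = binomial()))
    p <- predict(m, newdata = data[ho, , drop = FALSE], type = "response")
    aucs[run] <- auc_roc(p, y[ho])
    run <- run + 1L
  }
  list(auc = aucs, mean = mean(aucs), range = range(aucs), redrawn = redrawn)
}

#' Predict an occurrence-probability surface over a covariate grid
#'
#' Evaluates the logistic linear predictor `g(x)` per cell and converts it
#' to a probability `p(x) = exp(g) / (1 + exp(g))`. Also reports the total
#' area whose probability exceeds each threshold.
#'
#' @param fit A `logistic_model_fit` or named coefficient vector (intercept
#'   first).
#' @param grid A [covariate_grid()] supplying the selected covariates.
#' @param thresholds Probability thresholds for the area summary
#'   (default 0.5 and 0.9).
#' @return List with `prob` (matrix of probabilities) and `area`
#'   (data frame: `threshold`, `n_cells`, `area_km2`).
#' @export
predict_occurrence_grid <- function(fit, grid, thresholds = c(0.5, 0.9)) {
  coefs <- .fit_coefs(fit)
  g <- .grid_linpred(coefs, grid)
  p <- expit(g)
  cell_area <- grid$cell_km^2
  area <- data.frame(
    threshold = thresholds,
    n_cells = vapply(thresholds, function(th) sum(p > th, na.rm = TRUE), 0),
    stringsAsFactors = FALSE)
  area$area_km2 <- area$n_cells * cell_area
  list(prob = p, area = area)
}
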