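test_that("collinearity screen drops duplicates and keeps clean sets", {
  set.seed(1)
  d <- data.frame(y = rnorm(60), a = rnorm(60), c = rnorm(60))
  d$b <- d$a                     # exact duplicate of a
  d$y <- d$y + 0.8 * d$a         # a slightly more predictive than b
  out <- screen_collinearity(d, c("a", "b", "c"), "y")
  expect_setequal(out$retained, c("a", "c"))
  expect_equal(out$dropped$variable, "b")

  d2 <- data.frame(y = rnorm(60), a = rnorm(60), b = rnorm(60))
  out2 <- screen_collinearity(d2, c("a", "b"), "y")
  expect_identical(out2$retained, c("a", "b"))  # unchanged

  d2$k <- 1
  expect_error(screen_collinearity(d2, c("a", "k"), "y"), "constant")
})

test_that("collinearity screen matches an exhaustive pair-scan oracle", {
  set.seed(42)
  n <- 120
  base <- matrix(rnorm(n * 4), n)
  X <- cbind(base,
             base[, 1] + rnorm(n, 0, 0.3),   # correlated with column 1
             base[, 2] + rnorm(n, 0, 0.25),  # correlated with column 2
             rnorm(n), rnorm(n))
  colnames(X) <- paste0("c", 1:8)
  d <- data.frame(y = base[, 1] + 0.5 * base[, 2] + rnorm(n), X)

  # independent oracle: same greedy rule, re-implemented from scratch
  oracle <- function(df, cands, resp, thr) {
    kept <- cands
    repeat {
      cm <- abs(cor(df[kept]))
      diag(cm) <- 0
      if (max(cm) <= thr) return(kept)
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- kept[ij]
      ry <- abs(sapply(pair, function(v) cor(df[[v]], df[[resp]])))
      kept <- setdiff(kept, pair[which.min(ry)])
    }
  }
  out <- screen_collinearity(d, colnames(X), "y", threshold = 0.7)
  expect_setequal(out$retained, oracle(d, colnames(X), "y", 0.7))
  cm <- abs(out$cor_matrix[out$retained, out$retained])
  diag(cm) <- 0
  expect_true(all(cm <= 0.7))
})

test_that("single-candidate selection is degenerate by definition", {
  d <- make_linear_data(30, c(1, 2), seed = 1)
  out <- fit_all_subsets_linear(d, "v1", "y")
  expect_equal(out$n_models, 1L)
  expect_equal(out$ranking$delta_bic, 0)
  expect_equal(out$ranking$weight, 1)
})

test_that("all-subsets BIC ranking equals a brute-force enumeration oracle", {
  d <- make_linear_data(80, c(0.5, 1.2, -0.8, 0.6), sigma = 1, n_null = 3,
                        seed = 7)
  cands <- paste0("v", 1:6)
  out <- fit_all_subsets_linear(d, cands, "y", top = 63)
  expect_equal(out$n_models, 63L)  # 2^6 - 1 subsets

  # oracle: fit each subset with lm and rank by stats::BIC
  oracle <- do.call(rbind, lapply(seq_along(cands), function(k) {
    subs <- combn(cands, k, simplify = FALSE)
    data.frame(model = sapply(subs, paste, collapse = " + "),
               bic = sapply(subs, function(s)
                 BIC(lm(reformulate(s, "y"), data = d))))
  }))
  oracle <- oracle[order(oracle$bic), ]
  expect_equal(out$ranking$model, oracle$model)
  expect_equal(out$ranking$bic, oracle$bic, tolerance = 1e-8)
  expect_equal(out$ranking$delta_bic[1], 0)
  w <- exp(-out$ranking$delta_bic / 2)
  expect_equal(out$ranking$weight, w / sum(w), tolerance = 1e-12)
})

test_that("semi-partial formula reproduces printed model summaries", {
  # best density model: R^2 = 0.45, df_res = 75
  sr2 <- semi_partial_r2(0.45, c(5.76, 4.40, 2.68, -3.27), 75)
  expect_equal(round(sr2, 2), c(0.24, 0.14, 0.05, 0.08))
  expect_equal(semi_partial_r2(0.3, 0, 10), 0)
  expect_error(semi_partial_r2(0.5, 1, 0), "df_res")
  expect_error(semi_partial_r2(1.5, 1, 10), "\\[0, 1\\]")
})

test_that("semi-partial r2 equals the drop-one-covariate R2 increment", {
  d <- make_linear_data(50, c(1, 0.8, -0.5, 0.3), sigma = 1.5, seed = 11)
  full <- fit_all_subsets_linear(d, paste0("v", 1:3), "y")$best
  for (i in seq_along(full$covariates)) {
    reduced <- summary(lm(reformulate(full$covariates[-i], "y"), data = d))
    expect_equal(full$coefficients$sr2[i + 1],
                 full$r2 - reduced$r.squared, tolerance = 1e-8)
  }
})

test_that("BIC selection recovers the generating subset on synthetic data", {
  hits <- 0L
  for (s in 1:10) {
    d <- make_linear_data(500, c(0.5, 0.4, -0.35, 0.3), sigma = 1,
                          n_null = 2, seed = 100 + s)
    best <- fit_all_subsets_linear(d, paste0("v", 1:5), "y")$best
    if (setequal(best$covariates, c("v1", "v2", "v3"))) hits <- hits + 1L
  }
  expect_gte(hits, 8L)   # >= 80% of seeds
})

test_that("fitted coefficients recover the generating values within 3 SEs", {
  truth <- c(1, 0.8, -0.5, 0.3)
  d <- make_linear_data(300, truth, sigma = 1, seed = 21)
  fit <- fit_all_subsets_linear(d, paste0("v", 1:3), "y")$best
  expect_true(all(abs(fit$coefficients$estimate - truth) <
                    3 * fit$coefficients$se))
})

test_that("bootstrap bias is exactly zero for a perfectly fitted model", {
  d <- data.frame(x = 1:20)
  d$y <- 2 + 3 * d$x               # zero residuals: every resample refits
  out <- bootstrap_fit(d, "x", "y", reps = 200, seed = 1)
  expect_equal(out$bias, c(0, 0), tolerance = 1e-10)
  expect_equal(out$se_boot, c(0, 0), tolerance = 1e-10)
  expect_identical(attr(out, "reps"), 200)
  expect_identical(formals(bootstrap_fit)$reps, 10000L)
})

test_that("bootstrap bias is stable across seeds", {
  d <- make_linear_data(60, c(1, 0.7, -0.4), sigma = 1, seed = 5)
  b1 <- bootstrap_fit(d, c("v1", "v2"), "y", reps = 2000, seed = 1)
  b2 <- bootstrap_fit(d, c("v1", "v2"), "y", reps = 2000, seed = 2)
  # Monte Carlo SE of each bias estimate is se_boot / sqrt(reps)
  mc_se <- sqrt(b1$se_boot^2 + b2$se_boot^2) / sqrt(2000)
  expect_true(all(abs(b1$bias - b2$bias) < 4 * mc_se))
})

test_that("model reports serialize the fit summary as JSON", {
  skip_if_not_installed("jsonlite")
  d <- make_linear_data(40, c(1, 0.5), seed = 2)
  fit <- fit_all_subsets_linear(d, "v1", "y")$best
  path <- withr::local_tempfile(fileext = ".json")
  write_model_report(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$r2, fit$r2, tolerance = 1e-10)
  expect_equal(length(back$coefficients), 2)
})

test_that("grid prediction applies the published density coefficients", {
  coefs <- setNames(density_model_reference()$estimate,
                    c("(Intercept)", "TEMP", "NPP_MEAN", "NPP_SD", "NA_SA"))
  g <- make_grid(list(TEMP = matrix(26, 1, 1), NPP_MEAN = matrix(1000, 1, 1),
                      NPP_SD = matrix(50, 1, 1), NA_SA = matrix(2, 1, 1)))
  pred <- predict_density_grid(coefs, g)
  expect_equal(pred[1, 1],
               -8.07747 + 0.38911 * 26 + 0.00136 * 1000 + 0.01026 * 50 -
                 1.07356 * 2)

  g0 <- make_grid(list(TEMP = matrix(0, 1, 1), NPP_MEAN = matrix(0, 1, 1),
                       NPP_SD = matrix(0, 1, 1), NA_SA = matrix(1, 1, 1)))
  expect_equal(predict_density_grid(coefs, g0)[1, 1], 0)  # clamped
  expect_equal(predict_density_grid(coefs, g0, clamp = FALSE)[1, 1],
               -8.07747 - 1.07356)
})

test_that("grid prediction propagates missing cells and names absent layers", {
  coefs <- c(`(Intercept)` = 1, a = 2)
  vals <- matrix(c(1, NA, 3, 4), 2, 2)
  g <- make_grid(list(a = vals))
  pred <- predict_density_grid(coefs, g)
  expect_true(is.na(pred[2, 1]))
  expect_equal(pred[1, 1], 3)
  const <- make_grid(list(a = matrix(2, 3, 4)))
  expect_true(all(predict_density_grid(coefs, const) == 5))  # constant grid
  expect_error(predict_density_grid(c(`(Intercept)` = 1, zz = 1), g),
               "zz")
})
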