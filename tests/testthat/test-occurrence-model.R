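test_that("thinning collapses near-coincident points and keeps sparse sets", {
  pts <- data.frame(longitude = c(-60, -60.0001, -59), latitude = c(-3, -3, -3))
  expect_equal(nrow(thin_points(pts, 5)), 2)

  far <- data.frame(longitude = seq(-60, -55, by = 1), latitude = -3)
  expect_identical(thin_points(far, 5), far)   # all >= 5 km apart

  bad <- data.frame(longitude = 0, latitude = 95)
  expect_error(thin_points(bad), "latitude")
})

test_that("greedy thinning matches an all-pairs oracle and its invariant", {
  set.seed(33)
  # ~100 random points inside a 20 x 20 km box near the equator
  pts <- data.frame(longitude = -60 + runif(100, 0, 0.18),
                    latitude = runif(100, 0, 0.18))
  got <- thin_points(pts, 5)

  # oracle: literal greedy scan with an independent haversine
  kept <- 1L
  for (i in 2:100) {
    d <- oracle_haversine_km(pts$longitude[kept], pts$latitude[kept],
                             pts$longitude[i], pts$latitude[i])
    if (all(d >= 5)) kept <- c(kept, i)
  }
  expect_identical(got, pts[kept, ])

  # no retained pair is closer than the rule
  n <- nrow(got)
  for (i in seq_len(n - 1)) {
    d <- oracle_haversine_km(got$longitude[i], got$latitude[i],
                             got$longitude[(i + 1):n],
                             got$latitude[(i + 1):n])
    expect_true(all(d >= 5 - 1e-6))
  }
})

test_that("pseudo-absences sample eligible cells without replacement", {
  mask <- matrix(TRUE, 40, 30)
  g <- make_grid(list(z = matrix(0, 40, 30)), cell_km = 10)
  pa <- generate_pseudo_absences(g, mask, seed = 1)
  expect_equal(nrow(pa), 1000)         # default n
  expect_false(anyDuplicated(pa$cell) > 0)
  expect_true(all(pa$presence == 0))
  expect_true(all(pa$source == "pseudo-absence"))
  expect_identical(generate_pseudo_absences(g, mask, seed = 9),
                   generate_pseudo_absences(g, mask, seed = 9))

  small <- matrix(FALSE, 40, 30); small[1:5, 1] <- TRUE
  all5 <- generate_pseudo_absences(g, small, n = 5)
  expect_equal(sort(all5$cell), which(small))  # exactly-n mask: all cells
  expect_error(generate_pseudo_absences(g, small, n = 6), "eligible")
})

test_that("pseudo-absence points sit at cell centres", {
  g <- make_grid(list(z = matrix(0, 2, 2)), cell_km = 10, xll = 100, yll = 200)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)  # top-left cell
  pa <- generate_pseudo_absences(g, mask, n = 1)
  expect_equal(pa$x, 105)
  expect_equal(pa$y, 215)   # row 1 is the northern row
})

test_that("Nagelkerke R2 has the right endpoints and hand-computed value", {
  expect_equal(nagelkerke_r2(-10, -10, 20), 0)
  expect_equal(nagelkerke_r2(-200, 0, 100), 1)  # perfect fit saturates at 1
  expect_error(nagelkerke_r2(-5, -4, 0), "positive")

  # 4-point toy: y = (1,1,0,0); model probs (0.8, 0.6, 0.3, 0.2);
  # frozen hand computation: l0 = 4 log(1/2), l1 = log(.8)+log(.6)+log(.7)+log(.8)
  l0 <- 4 * log(0.5)
  l1 <- log(0.8) + log(0.6) + log(0.7) + log(0.8)
  expect_equal(nagelkerke_r2(l0, l1, 4), 0.690402708491, tolerance = 1e-10)
})

test_that("AUC is the tie-aware pairwise exceedance probability", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")

  set.seed(17)
  scores <- round(rnorm(20), 1)        # rounding forces some ties
  labels <- rbinom(20, 1, 0.5)
  labels[1:2] <- c(0, 1)               # ensure both classes
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  expect_equal(auc_roc(scores, labels), wins / (length(pos) * length(neg)))

  # invariance under strictly monotone transforms of the scores
  expect_equal(auc_roc(exp(3 * scores), labels), auc_roc(scores, labels))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, plogis(scores))
  expect_equal(auc_roc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("all-subsets logistic ranking matches a brute-force oracle", {
  d <- make_logistic_data(300, c(0, 1.2, -0.9, 0, 0, 0.8), seed = 19)
  cands <- paste0("v", 1:5)
  out <- fit_all_subsets_logistic(d, cands, top = 31)
  expect_equal(out$n_models, 31L)

  oracle <- do.call(rbind, lapply(seq_along(cands), function(k) {
    subs <- combn(cands, k, simplify = FALSE)
    data.frame(model = sapply(subs, paste, collapse = " + "),
               bic = sapply(subs, function(s)
                 BIC(glm(reformulate(s, "presence"), data = d,
                         family = binomial()))))
  }))
  oracle <- oracle[order(oracle$bic), ]
  expect_equal(out$ranking$model, oracle$model)
  expect_equal(out$ranking$bic, oracle$bic, tolerance = 1e-8)

  one <- fit_all_subsets_logistic(d, "v1")
  expect_equal(one$ranking$weight, 1)
})

test_that("odds ratios are exp(coefficient) and match the printed table", {
  expect_equal(round(exp(1.19062), 2), 3.29)
  d <- make_logistic_data(400, c(-0.5, 1, 0.6), seed = 23)
  best <- fit_all_subsets_logistic(d, c("v1", "v2"))$best
  expect_equal(best$coefficients$odds_ratio,
               exp(best$coefficients$estimate))
  ref <- occurrence_model_reference()
  consistent <- ref$term %in% c("PREC", "CANOPY_MEAN", "HPDENLG", "HFOOTP",
                                "PRAR", "NA_SA")
  expect_equal(round(exp(ref$estimate[consistent]), 2),
               ref$odds_ratio_printed[consistent])
  expect_false(ref$or_consistent[ref$term == "TEMP"])
})

test_that("complete separation is flagged but the model is retained", {
  d <- data.frame(v1 = c(-(10:1), 1:10) / 2,
                  presence = rep(c(0, 1), each = 10))
  expect_warning(out <- fit_all_subsets_logistic(d, "v1"), "separation")
  expect_true(out$best$separated)
  expect_equal(out$best$auc, 1)
})

test_that("ROC points trace the classification trade-off", {
  sc <- c(0.9, 0.8, 0.3, 0.1); lb <- c(1, 1, 0, 0)
  r <- roc_points(sc, lb)
  expect_equal(r$sensitivity[1], 1)   # threshold -Inf: all positive
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[nrow(r)], 0)
  expect_equal(r$specificity[nrow(r)], 1)
  # a separating threshold achieves perfect classification
  expect_true(any(r$sensitivity == 1 & r$specificity == 1))
})

test_that("repeated 75/25 cross-validation returns one AUC per run", {
  d <- make_logistic_data(200, c(0, 1.5), seed = 31)
  cv <- cross_validate(d, "v1", n_runs = 10, seed = 4)
  expect_length(cv$auc, 10)
  expect_equal(cv$mean, mean(cv$auc))
  cv2 <- cross_validate(d, "v1", n_runs = 10, seed = 4)
  expect_identical(cv$auc, cv2$auc)     # reproducible under a fixed seed

  sep <- data.frame(v1 = c(-(20:1), 1:20), presence = rep(0:1, each = 20))
  cvs <- cross_validate(sep, "v1", n_runs = 5, seed = 1)
  expect_true(all(cvs$auc == 1))        # separable data scores perfectly
})

test_that("logistic recovery at the empirical sample size", {
  truth <- c(-0.5, 1.1, -0.7, 0.6)
  d <- make_logistic_data(3377, truth, seed = 41)
  best <- fit_all_subsets_logistic(d, paste0("v", 1:3))$best
  expect_setequal(best$covariates, paste0("v", 1:3))
  expect_true(all(abs(best$coefficients$estimate - truth) <
                    3 * best$coefficients$se))
  # holdout AUC close to the generating model's AUC on a large fresh sample
  fresh <- make_logistic_data(20000, truth, seed = 43)
  eta <- truth[1] + as.matrix(fresh[paste0("v", 1:3)]) %*% truth[-1]
  auc_true <- auc_roc(drop(eta), fresh$presence)
  cv <- cross_validate(d, paste0("v", 1:3), n_runs = 5, seed = 2)
  expect_lt(abs(cv$mean - auc_true), 0.03)
})

test_that("probability surfaces convert logits with saturation and inverse", {
  coefs <- c(`(Intercept)` = 0, a = 1)
  g <- make_grid(list(a = matrix(c(0, 20, -20, 1), 2, 2)), cell_km = 10)
  out <- predict_occurrence_grid(coefs, g)
  expect_equal(out$prob[1, 1], 0.5)
  expect_gt(out$prob[2, 1], 0.9999)
  expect_lt(out$prob[1, 2], 0.0001)
  # inverse identity, at the precision double-precision probabilities allow
  gvals <- seq(-12, 12, by = 0.5)
  expect_lt(max(abs(logit(expit(gvals)) - gvals)), 1e-9)
  gsat <- seq(-30, 30, by = 0.5)
  expect_lt(max(abs(logit(expit(gsat)) - gsat)), 2e-3)

  # area above thresholds counts cells times cell area
  expect_equal(out$area$n_cells[out$area$threshold == 0.5], 2)
  expect_equal(out$area$area_km2[out$area$threshold == 0.5], 200)
  expect_equal(out$area$n_cells[out$area$threshold == 0.9], 1)
})
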