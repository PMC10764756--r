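test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(51)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(x, x)$rho, 1)
  # constant covariate drops out
  expect_equal(partial_spearman(x, y, covariates = rep(3, 40))$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("partial Spearman removes a shared confounder", {
  set.seed(52)
  z <- rnorm(500)
  x <- exp(z) + 0.3 * rnorm(500)     # monotone in z
  y <- z^3 + 0.3 * rnorm(500)        # monotone in z
  raw <- cor(x, y, method = "spearman")
  part <- partial_spearman(x, y, covariates = z)$rho
  expect_gt(raw, 0.5)
  expect_lt(abs(part), 0.1)
})

test_that("classification metrics follow the contingency arithmetic", {
  # perfect separation
  m <- classification_metrics(c(0.1, 0.2, 0.8, 0.9),
                              c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$accuracy, 100)
  expect_equal(m$auc, 1)
  # TP=3 FN=1 FP=1 TN=3 via indices around the threshold
  idx <- c(0.1, 0.2, 0.3, 0.7, 0.4, 0.8, 0.9, 0.6)
  imp <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m2 <- classification_metrics(idx, imp)
  expect_equal(c(m2$tp, m2$fn, m2$fp, m2$tn), c(3, 1, 1, 3))
  expect_equal(m2$sensitivity, 75)
  expect_equal(m2$specificity, 75)
  expect_equal(m2$odds_ratio, 9)
  expect_false(m2$odds_ratio_corrected)
  # boundary convention: exactly 0.5 is called normal
  m3 <- classification_metrics(c(0.5, 0.5, 0.5, 0.5),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$specificity, 100)
  expect_error(classification_metrics(c(0.1, 0.2), c(TRUE, TRUE)), "classes")
})

test_that("rank AUC equals ROC trapezoid integration and flips with labels", {
  set.seed(53)
  for (i in 1:10) {
    idx <- round(runif(30), 2)           # ties included
    imp <- runif(30) < 0.4
    if (!any(imp) || all(imp)) next
    m <- classification_metrics(idx, imp)
    expect_equal(m$auc, trapezoid_auc(idx, imp), tolerance = 1e-10)
    swapped <- classification_metrics(idx, !imp)
    expect_equal(swapped$auc, 1 - m$auc, tolerance = 1e-10)
    expect_equal(swapped$sensitivity, 100 - m$specificity)
  }
})

test_that("zero confusion cells trigger the Haldane-Anscombe correction", {
  m <- classification_metrics(c(0.1, 0.2, 0.8, 0.9, 0.45),
                              c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_true(m$odds_ratio_corrected)
  expect_true(is.finite(m$odds_ratio))
})

test_that("regression block: exact fits, F tests, AIC penalty, LRT", {
  x <- seq(0, 1, length.out = 50)
  lin <- regression_models(x, 3 + 2 * x)
  expect_equal(lin$linear$r2, 1, tolerance = 1e-10)
  expect_equal(lin$linear$rmse, 0, tolerance = 1e-6)
  quad <- regression_models(x, 1 - 4 * (x - 0.5)^2)
  expect_equal(quad$quadratic$r2, 1, tolerance = 1e-10)
  expect_lt(quad$lrt_p, 0.001)
  # quadratic never fits worse than linear
  set.seed(54)
  y <- 2 * x + rnorm(50)
  r <- regression_models(x, y)
  expect_gte(r$quadratic$r2, r$linear$r2)
  expect_true(all(c(r$linear$rmse, r$quadratic$rmse) >= 0))
  # on pure-linear data the quadratic usually pays its AIC penalty
  worse <- sapply(1:40, function(s) {
    set.seed(400 + s)
    y <- 2 * x + rnorm(50)
    r <- regression_models(x, y)
    r$quadratic$aic > r$linear$aic
  })
  expect_gte(mean(worse), 0.6)
  expect_error(regression_models(rep(0.5, 10), rnorm(10)), "constant")
})

eval_fixture <- function(seed = 61) {
  scores <- c(18, 20, 21, 22, 24, 25, 26, 27, 28, 29, 30, 23)
  toy <- toy_cohort(scores, duration = 12, seed = seed)
  recs <- lapply(toy$recordings, preprocess_recording)
  configs <- list(E1 = list(band = c(4, 14), order = 4, dim = 2))
  list(recs = recs, table = toy$table, configs = configs)
}

test_that("LOOCV produces one out-of-fold index per subject and separates", {
  fx <- eval_fixture()
  rep <- loocv(fx$recs, fx$table, fx$configs)
  expect_length(rep$indices, nrow(fx$table))
  expect_setequal(names(rep$indices), fx$table$id)
  expect_true(all(rep$indices >= 0 & rep$indices <= 1))
  expect_true(is.finite(rep$spearman$rho))
  expect_true(rep$classification$auc > 0.5)  # informative electrode
})

test_that("k-fold CV is seed-reproducible and k = n matches LOOCV", {
  fx <- eval_fixture()
  k1 <- kfold_cv(fx$recs, fx$table, fx$configs, k = 4, rounds = 1, seed = 9)
  k2 <- kfold_cv(fx$recs, fx$table, fx$configs, k = 4, rounds = 1, seed = 9)
  expect_identical(k1$reports[[1]]$indices, k2$reports[[1]]$indices)
  kn <- kfold_cv(fx$recs, fx$table, fx$configs, k = nrow(fx$table),
                 rounds = 1, seed = 9)
  ln <- loocv(fx$recs, fx$table, fx$configs)
  expect_equal(kn$reports[[1]]$indices[names(ln$indices)], ln$indices,
               tolerance = 1e-12)
  expect_named(k1$summary, c("rho", "accuracy", "auc"))
  expect_error(kfold_cv(fx$recs, fx$table, fx$configs, k = 200), "exceeds")
})

test_that("randomization test permutes the score multiset; identity = LOOCV", {
  fx <- eval_fixture()
  id_rep <- randomization_test(fx$recs, fx$table, fx$configs, seed = 5,
                               identity = TRUE)
  base <- loocv(fx$recs, fx$table, fx$configs)
  expect_equal(id_rep$indices, base$indices, tolerance = 1e-12)
  expect_equal(id_rep$spearman$rho, base$spearman$rho, tolerance = 1e-12)
  r1 <- randomization_test(fx$recs, fx$table, fx$configs, seed = 5)
  r2 <- randomization_test(fx$recs, fx$table, fx$configs, seed = 5)
  expect_identical(r1$indices, r2$indices)
})

test_that("out-of-sample evaluation never refits on the test cohort", {
  fx <- eval_fixture()
  model <- fit_model(fx$recs, fx$table, fx$configs)
  # fresh cohort from the same generator family
  toy2 <- toy_cohort(c(19, 20, 22, 24, 25, 26, 27, 29, 30, 28),
                     duration = 12, seed = 62)
  recs2 <- lapply(toy2$recordings, preprocess_recording)
  ev <- out_of_sample(model, recs2, toy2$table)
  expect_equal(ev$scheme, "out_of_sample")
  expect_length(ev$indices, 10)
  # the fitted model is untouched by scoring: bit-identical serialization
  expect_identical(model_to_json(model),
                   model_to_json(fit_model(fx$recs, fx$table, fx$configs)))
  # indices equal direct scoring with the fixed model
  sc <- score_subjects(model, recs2)
  expect_equal(unname(ev$indices[sc$id]), sc$combined, tolerance = 1e-12)
})

test_that("electrode sweep returns one LOOCV point per count", {
  fx <- eval_fixture()
  search <- structure(list(
    E1 = list(electrode = "E1",
              config = list(band = c(4, 14), order = 4, dim = 2), rho = 0.8),
    E2 = list(electrode = "E2",
              config = list(band = c(4, 14), order = 3, dim = 1), rho = 0.1)),
    class = "leapd_search")
  sw <- electrode_sweep(fx$recs, fx$table, search, counts = 1:2)
  expect_equal(nrow(sw), 2)
  best_single <- loocv(fx$recs, fx$table,
                       list(E1 = search$E1$config))
  expect_equal(sw$auc[1], best_single$classification$auc, tolerance = 1e-12)
  expect_error(electrode_sweep(fx$recs, fx$table, search, counts = 1:3),
               "exceed")
})

test_that("truncation sweep: 100% point reproduces the untruncated LOOCV", {
  fx <- eval_fixture()
  sw <- truncation_sweep(fx$recs, fx$table, fx$configs,
                         fractions = c(50, 100))
  base <- loocv(fx$recs, fx$table, fx$configs)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$auc[sw$fraction == 100], base$classification$auc,
               tolerance = 1e-12)
  expect_equal(sw$rho[sw$fraction == 100], base$spearman$rho,
               tolerance = 1e-12)
  expect_error(truncation_sweep(fx$recs, fx$table, fx$configs, fractions = 1),
               "too few samples")
})
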