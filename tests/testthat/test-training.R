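make_table <- function(scores, score_name = "moca") {
  tab <- data.frame(id = sprintf("s%02d", seq_along(scores)),
                    age = 65 + seq_along(scores), sex = "M", group = "PD",
                    stringsAsFactors = FALSE)
  tab[[score_name]] <- scores
  tab
}

test_that("group splitting follows the fixed MoCA cutoff and median rule", {
  tab <- make_table(c(25, 26, 9, 30, 22))
  g <- split_groups(tab, "moca")
  expect_setequal(g$impaired, c("s01", "s03", "s05"))  # 25, 9, 22 all < 26
  expect_setequal(g$normal, c("s02", "s04"))           # 26 and 30 are normal
  expect_equal(g$cutoff, 26)
  # NIH-style median split: median itself lands in the high group
  tabn <- make_table(c(1, 2, 3, 4, 5), "pvt")
  gn <- split_groups(tabn, "pvt")
  expect_setequal(gn$impaired, c("s01", "s02"))
  expect_setequal(gn$normal, c("s03", "s04", "s05"))
  # missing scores excluded and reported
  tab$moca[2] <- NA
  g2 <- split_groups(tab, "moca")
  expect_equal(g2$excluded, "s02")
  expect_error(split_groups(make_table(c(10, 12, 14)), "moca"), "empty group")
})

test_that("fold assignment is a stratified partition, deterministic in the seed", {
  ids <- sprintf("s%02d", 1:20)
  imp <- rep(c(TRUE, FALSE), each = 10)
  f1 <- make_folds(ids, imp, 5, seed = 11)
  f2 <- make_folds(ids, imp, 5, seed = 11)
  expect_identical(f1, f2)
  expect_setequal(names(f1), ids)
  expect_true(all(table(f1) == 4))
  # stratification: every fold carries both groups
  for (k in 1:5) {
    fold_ids <- names(f1)[f1 == k]
    expect_true(any(imp[match(fold_ids, ids)]))
    expect_true(any(!imp[match(fold_ids, ids)]))
  }
  expect_false(identical(f1, make_folds(ids, imp, 5, seed = 12)))
  expect_error(make_folds(ids, imp, 1, 1), "fold count")
})

test_that("out-of-fold scoring never sees the held-out subject", {
  scores <- c(20, 21, 22, 23, 27, 28, 29, 30)
  toy <- toy_cohort(scores, seed = 41)
  cfg <- list(band = c(4, 14), order = 4, dim = 2)
  recs <- lapply(toy$recordings, preprocess_recording)
  idx <- single_electrode_index_cv(recs, toy$table, "E1", cfg,
                                   folds = 4, seed = 7)
  expect_setequal(names(idx), toy$table$id)
  expect_true(all(idx >= 0 & idx <= 1))
  # determinism
  idx2 <- single_electrode_index_cv(recs, toy$table, "E1", cfg,
                                    folds = 4, seed = 7)
  expect_identical(idx, idx2)
  # leakage: perturbing one held-out subject's EEG leaves the indices of
  # the other subjects in its fold unchanged (their model excludes the fold)
  groups <- split_groups(toy$table, "moca")
  ids <- c(groups$impaired, groups$normal)
  fa <- make_folds(ids, ids %in% groups$impaired, 4, seed = 7)
  victim <- names(fa)[fa == 1][1]
  mate <- setdiff(names(fa)[fa == 1], victim)[1]
  recs2 <- recs
  recs2[[victim]]$data[, "E1"] <- rev(recs2[[victim]]$data[, "E1"])
  idx3 <- single_electrode_index_cv(recs2, toy$table, "E1", cfg,
                                    folds = 4, seed = 7)
  expect_identical(idx3[mate], idx[mate])
  expect_false(identical(idx3[victim], idx[victim]))
})

test_that("degenerate folds that empty a training group are an error", {
  scores <- c(20, 21, 27, 28)   # 2 impaired, 2 normal
  toy <- toy_cohort(scores, seed = 42)
  recs <- lapply(toy$recordings, preprocess_recording)
  cfg <- list(band = c(4, 14), order = 4, dim = 1)
  # 2 folds put one member of each group per fold: training halves have a
  # single point per group, below the 2 needed to span a subspace
  expect_error(
    single_electrode_index_cv(recs, toy$table, "E1", cfg, folds = 2, seed = 1),
    "at least 2|empty")
})

test_that("grid search returns the singleton and is deterministic", {
  scores <- c(18, 20, 22, 24, 27, 28, 29, 30, 19, 26)
  toy <- toy_cohort(scores, seed = 43)
  recs <- lapply(toy$recordings, preprocess_recording)
  g1 <- leapd_grid(orders = 4L, max_dim = 2)
  g1$bands <- rbind(c(4, 14))
  r1 <- grid_search_electrode(recs, toy$table, "E1", g1, folds = 5, seed = 3)
  expect_equal(r1$config$band, c(4, 14))
  expect_equal(r1$config$order, 4L)
  g2 <- leapd_grid(orders = c(3L, 4L), max_dim = 2)
  g2$bands <- rbind(c(3, 8), c(4, 14), c(20, 30))
  r2 <- grid_search_electrode(recs, toy$table, "E1", g2, folds = 5, seed = 3)
  r3 <- grid_search_electrode(recs, toy$table, "E1", g2, folds = 5, seed = 3)
  expect_identical(r2, r3)
  expect_true(r2$rho >= r1$rho - 1e-12 || !identical(r2$config, r1$config))
  expect_error(grid_search_electrode(recs, toy$table, "E1",
                                     list(bands = matrix(0, 0, 2)), 5, 3),
               "empty")
})

test_that("the search finds the informative band", {
  # groups differ only through an oscillation inside 6-11 Hz: the winning
  # band should overlap it rather than the pure-noise 20-30 Hz band
  hits <- sapply(1:3, function(s) {
    scores <- c(17, 19, 21, 23, 25, 26, 27, 28, 29, 30)
    toy <- toy_cohort(scores, duration = 20, seed = 100 + s)
    recs <- lapply(toy$recordings, preprocess_recording)
    g <- leapd_grid(orders = 4L, max_dim = 3)
    g$bands <- rbind(c(5, 12), c(20, 30))
    r <- grid_search_electrode(recs, toy$table, "E1", g, folds = 5, seed = s)
    identical(as.numeric(r$config$band), c(5, 12))
  })
  expect_gte(sum(hits), 2)
})

test_that("electrode selection ranks by rho with stable tie-break", {
  res <- structure(list(
    A = list(electrode = "A", config = list(), rho = 0.5),
    B = list(electrode = "B", config = list(), rho = 0.8),
    C = list(electrode = "C", config = list(), rho = 0.5),
    D = list(electrode = "D", config = list(), rho = 0.9)),
    class = "leapd_search")
  expect_equal(select_electrodes(res, 1), "D")
  expect_equal(select_electrodes(res, 4), c("D", "B", "A", "C"))
  expect_error(select_electrodes(res, 5), "exceeds")
  expect_error(select_electrodes(res, 0), "at least 1")
})

test_that("fitted models score in [0,1] and survive JSON round-trips", {
  scores <- c(18, 20, 22, 24, 27, 28, 29, 30)
  toy <- toy_cohort(scores, seed = 44)
  recs <- lapply(toy$recordings, preprocess_recording)
  configs <- list(E1 = list(band = c(4, 14), order = 4, dim = 2),
                  E2 = list(band = c(4, 14), order = 3, dim = 1))
  model <- fit_model(recs, toy$table, configs)
  sc <- score_subjects(model, recs)
  expect_true(all(sc$combined >= 0 & sc$combined <= 1))
  expect_equal(sc$predicted, ifelse(sc$combined < 0.5, "impaired", "normal"))
  path <- file.path(tempdir(), "model.json")
  model_to_json(model, path)
  back <- model_from_json(path)
  sc2 <- score_subjects(back, recs)
  expect_equal(sc2$combined, sc$combined, tolerance = 1e-12)
  expect_equal(back$electrodes, model$electrodes)
  expect_equal(back$cutoff, 26)
})
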