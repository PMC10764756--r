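#' Partial Spearman correlation
#'
#' Rank-transforms every variable (average ranks for ties), linearly adjusts
#' the two rank vectors for the covariate ranks, and correlates the
#' residuals. With no covariates this reduces exactly to the plain Spearman
#' rho. The two-sided p value uses the t approximation with
#' `df = n - 2 - #covariates`.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param covariates optional numeric vector or matrix of covariates (e.g.
#'   age) with `n` rows.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector")
  rx <- rank(x); ry <- rank(y)
  n_cov <- 0L
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (nrow(Z) != n) stop("covariates must have one row per observation")
    Z <- apply(Z, 2, rank)
    Z <- Z[, apply(Z, 2, stats::sd) > 0, drop = FALSE]  # constants drop out
    n_cov <- ncol(Z)
    if (n_cov > 0) {
      rx <- stats::lm.fit(cbind(1, Z), rx)$residuals
      ry <- stats::lm.fit(cbind(1, Z), ry)$residuals
    }
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - n_cov
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = p, n = n)
}

#' Classification metrics for LEAPD indices
#'
#' The impaired class is the positive class and is predicted when the index
#' is strictly below the threshold (an index exactly at 0.5 is called
#' normal). The AUC is the rank (Mann-Whitney) statistic treating impaired
#' as the low-index class; the odds ratio uses the Haldane-Anscombe 0.5
#' correction when any confusion cell is zero (flagged).
#'
#' @param indices numeric vector of indices in `[0, 1]`.
#' @param impaired logical vector: `TRUE` for impaired subjects.
#' @param threshold decision threshold (default 0.5).
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (all percent), `auc`, `odds_ratio`, `odds_ratio_corrected`, confusion
#'   counts `tp`, `fn`, `fp`, `tn`.
#' @export
classification_metrics <- function(indices, impaired, threshold = 0.5) {
  if (!any(impaired) || all(impaired))
    stop("both classes must be present (AUC undefined otherwise)")
  pred_imp <- indices < threshold
  tp <- sum(pred_imp & impaired); fn <- sum(!pred_imp & impaired)
  fp <- sum(pred_imp & !impaired); tn <- sum(!pred_imp & !impaired)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  # P(index_normal > index_impaired), ties counted half
  r <- rank(indices)
  n1 <- sum(impaired); n2 <- sum(!impaired)
  auc <- (sum(r[!impaired]) - n2 * (n2 + 1) / 2) / (n1 * n2)
  corrected <- any(c(tp, fn, fp, tn) == 0)
  cells <- c(tp, fn, fp, tn) + if (corrected) 0.5 else 0
  list(accuracy = pct(tp + tn, tp + tn + fp + fn),
       sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
       auc = auc,
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       odds_ratio_corrected = corrected,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Linear and quadratic regressions of score on index
#'
#' Ordinary least squares of `score ~ index` and
#' `score ~ index + index^2`. Reports, per model: R-squared, residual RMSE
#' on the raw score scale and with both variables min-max scaled to `[0, 1]`
#' (two conventions, both emitted), the F statistic against the
#' intercept-only model with its p value, and the Gaussian AIC
#' `n * log(RSS / n) + 2 * (params + 1)`. A likelihood-ratio test compares
#' the quadratic against the linear model (`chi^2`, 1 df).
#'
#' @param index numeric predictor (combined LEAPD index).
#' @param score numeric response (cognitive score), length `n >= 4`.
#' @return list with `linear` and `quadratic` blocks and `lrt_p`.
#' @export
regression_models <- function(index, score) {
  n <- length(index)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(index) == 0) stop("constant predictor")
  scale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  idx_s <- scale01(index); sc_s <- scale01(score)
  fit_block <- function(form_raw, form_scaled, p) {
    fr <- stats::lm(form_raw)
    fs <- stats::lm(form_scaled)
    rss <- sum(stats::residuals(fr)^2)
    tss <- sum((score - mean(score))^2)
    r2 <- 1 - rss / tss
    fstat <- if (tss > rss) ((tss - rss) / p) / (rss / (n - p - 1)) else Inf
    fp <- stats::pf(fstat, p, n - p - 1, lower.tail = FALSE)
    list(r2 = r2,
         rmse = sqrt(mean(stats::residuals(fr)^2)),
         rmse_scaled = sqrt(mean(stats::residuals(fs)^2)),
         f_statistic = fstat, f_p = fp,
         aic = n * log(rss / n) + 2 * (p + 1),
         rss = rss)
  }
  lin <- fit_block(score ~ index, sc_s ~ idx_s, 1L)
  quad <- fit_block(score ~ index + I(index^2), sc_s ~ idx_s + I(idx_s^2), 2L)
  lrt <- n * (log(lin$rss / n) - log(quad$rss / n))
  list(linear = lin[setdiff(names(lin), "rss")],
       quadratic = quad[setdiff(names(quad), "rss")],
       lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

# Metrics bundle from per-subject combined indices + subject table.
# Age-adjusted partial Spearman for the correlation block; classification
# against the score cutoff; regressions of score on index.
eval_report <- function(indices, table, score_name, cutoff, scheme) {
  tab <- table[match(names(indices), table$id), ]
  score <- tab[[score_name]]
  keep <- !is.na(score)
  idx <- indices[keep]; score <- score[keep]; age <- tab$age[keep]
  sp <- partial_spearman(idx, score, covariates = age)
  cls <- classification_metrics(idx, impaired = score < cutoff)
  reg <- regression_models(idx, score)
  structure(
    list(scheme = scheme, indices = indices, score_name = score_name,
         cutoff = cutoff, spearman = sp, classification = cls,
         regression = reg),
    class = "leapd_eval")
}

#' @export
print.leapd_eval <- function(x, ...) {
  cat(sprintf("LEAPD evaluation (%s, %s, n = %d)\n", x$scheme,
              toupper(x$score_name), length(x$indices)))
  cat(sprintf("  age-adjusted Spearman rho = %.3f (p = %.3g)\n",
              x$spearman$rho, x$spearman$p))
  cat(sprintf("  accuracy %.2f%%, AUC %.3f, sens %.2f%%, spec %.2f%%\n",
              x$classification$accuracy, x$classification$auc,
              x$classification$sensitivity, x$classification$specificity))
  cat(sprintf("  linear R2 %.3f (RMSE %.3f scaled), quadratic R2 %.3f, LRT p %.3g\n",
              x$regression$linear$r2, x$regression$linear$rmse_scaled,
              x$regression$quadratic$r2, x$regression$lrt_p))
  invisible(x)
}

# Normalize a model spec (either a fitted leapd_model or a bare list of
# configs) to the named config list used by the CV schemes.
spec_configs <- function(model_spec) {
  if (inherits(model_spec, "leapd_model")) model_spec$configs
  else model_spec
}

# LOOCV engine shared by loocv() and randomization_test(): per electrode the
# LPC matrix is computed once (held-out subjects' raw LPC vectors do not
# depend on the fit), then for each subject the subspace pair is refitted
# without that subject.
loocv_indices <- function(recordings, table, configs, score_name) {
  groups <- split_groups(table, score_name)
  ids <- c(groups$impaired, groups$normal)
  ids <- ids[ids %in% names(recordings)]
  imp <- ids %in% groups$impaired
  if (sum(imp) < 3 || sum(!imp) < 3)
    stop("leave-one-out requires at least 3 subjects per group")
  per <- matrix(NA_real_, length(ids), length(configs),
                dimnames = list(ids, names(configs)))
  for (el in names(configs)) {
    cfg <- configs[[el]]
    V <- lpc_matrix(recordings, ids, el, cfg$band, cfg$order)
    for (i in seq_along(ids)) {
      train <- ids[-i]
      pair <- fit_pair(V, intersect(train, groups$impaired),
                       intersect(train, groups$normal), cfg$dim)
      per[i, el] <- leapd_index(V[ids[i], ], pair)
    }
  }
  list(combined = stats::setNames(apply(per, 1, combine_indices), ids),
       per_electrode = per, cutoff = groups$cutoff)
}

#' Leave-one-out cross-validation
#'
#' For each subject, the per-electrode subspace pairs are refitted on all
#' remaining subjects (electrode configurations held fixed) and the
#' subject's combined index is computed out of fold. Metrics are then taken
#' over all subjects.
#'
#' @param recordings named list of preprocessed recordings.
#' @param table subject data.frame.
#' @param model_spec a `leapd_model` or a named list of per-electrode
#'   configurations (`band`, `order`, `dim`).
#' @param score_name cognitive score.
#' @return a `leapd_eval` report.
#' @export
loocv <- function(recordings, table, model_spec, score_name = "moca") {
  configs <- spec_configs(model_spec)
  res <- loocv_indices(recordings, table, configs, score_name)
  eval_report(res$combined, table, score_name, res$cutoff, "loocv")
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `rounds` independent stratified shuffles of the subjects into `k`
#' folds; in each round every subject is scored by subspace pairs fitted on
#' the other folds, and a full metrics report is produced per round.
#'
#' @inheritParams loocv
#' @param k number of folds.
#' @param rounds number of independent shuffling rounds.
#' @param seed integer seed; round `r` uses `seed + r - 1`.
#' @return list of class `leapd_kfold`: `reports` (one `leapd_eval` per
#'   round) and `summary` (mean and sd of the headline metrics).
#' @export
kfold_cv <- function(recordings, table, model_spec, k = 10, rounds = 1,
                     seed = 1, score_name = "moca") {
  if (k < 2) stop("k must be at least 2")
  if (rounds < 1) stop("rounds must be at least 1")
  configs <- spec_configs(model_spec)
  groups <- split_groups(table, score_name)
  ids <- c(groups$impaired, groups$normal)
  ids <- ids[ids %in% names(recordings)]
  if (k > length(ids))
    stop(sprintf("k = %d exceeds the %d available subjects", k, length(ids)))
  Vs <- lapply(names(configs), function(el) {
    cfg <- configs[[el]]
    lpc_matrix(recordings, ids, el, cfg$band, cfg$order)
  })
  names(Vs) <- names(configs)
  reports <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    fold_assign <- make_folds(ids, ids %in% groups$impaired, k,
                              seed + r - 1L)
    per <- vapply(names(configs), function(el)
      oof_indices(Vs[[el]], groups, fold_assign, configs[[el]]$dim)[ids],
      numeric(length(ids)))
    combined <- stats::setNames(apply(as.matrix(per), 1, combine_indices),
                                ids)
    reports[[r]] <- eval_report(combined, table, score_name, groups$cutoff,
                                sprintf("kfold(k=%d, round=%d)", k, r))
  }
  pull <- function(f) vapply(reports, f, 0)
  metrics <- list(
    rho = pull(function(x) x$spearman$rho),
    accuracy = pull(function(x) x$classification$accuracy),
    auc = pull(function(x) x$classification$auc))
  structure(
    list(reports = reports,
         summary = lapply(metrics, function(v)
           c(mean = mean(v), sd = stats::sd(v)))),
    class = "leapd_kfold")
}

#' Randomization (label-shuffling) test
#'
#' Permutes the cognitive scores among subjects once (seeded), then re-runs
#' the full leave-one-out pipeline on the shuffled table: training groups
#' are re-split from the shuffled scores and all metrics are computed
#' against them. Under the null the index should carry no information about
#' the shuffled scores.
#'
#' @inheritParams loocv
#' @param seed integer seed for the permutation.
#' @param identity if `TRUE`, use the identity permutation (testing hook;
#'   the report then equals the plain LOOCV report).
#' @return a `leapd_eval` report with scheme `"randomization"`.
#' @export
randomization_test <- function(recordings, table, model_spec, seed = 1,
                               score_name = "moca", identity = FALSE) {
  shuffled <- table
  if (!identity) {
    set.seed(as.integer(seed))
    perm <- sample(nrow(table))
    shuffled[[score_name]] <- table[[score_name]][perm]
  }
  configs <- spec_configs(model_spec)
  res <- loocv_indices(recordings, shuffled, configs, score_name)
  rep <- eval_report(res$combined, shuffled, score_name, res$cutoff,
                     "randomization")
  rep
}

#' Out-of-sample evaluation of a fixed model
#'
#' Scores a separate, never-seen cohort with an already-fitted model (no
#' refitting of any kind: subspaces, configurations and electrode selection
#' all come from the training cohort) and computes the full metrics bundle
#' against the new cohort's scores.
#'
#' @param model a fitted [fit_model()] result.
#' @param recordings named list of preprocessed recordings for the test
#'   cohort.
#' @param table subject data.frame for the test cohort.
#' @return a `leapd_eval` report with scheme `"out_of_sample"`.
#' @export
out_of_sample <- function(model, recordings, table) {
  sc <- score_subjects(model, recordings)
  indices <- stats::setNames(sc$combined, sc$id)
  keep <- names(indices)[names(indices) %in% table$id]
  eval_report(indices[keep], table, model$score_name, model$cutoff,
              "out_of_sample")
}

#' Electrode-count robustness sweep
#'
#' For each count `c`, combines the top `c` electrodes (ranked high to low
#' by their search rho) and evaluates the combined index by leave-one-out
#' cross-validation.
#'
#' @param recordings named list of preprocessed recordings.
#' @param table subject data.frame.
#' @param search a `leapd_search` result ranking all candidate electrodes.
#' @param counts electrode counts to sweep (default all of `1..L`).
#' @param score_name cognitive score.
#' @return data.frame of class `leapd_sweep` with columns `n_electrodes`,
#'   `rho`, `accuracy`, `auc`.
#' @export
electrode_sweep <- function(recordings, table, search,
                            counts = seq_along(search),
                            score_name = "moca") {
  if (max(counts) > length(search))
    stop("counts exceed the number of searched electrodes")
  ranked <- select_electrodes(search, length(search))
  rows <- lapply(counts, function(cc) {
    configs <- lapply(search[ranked[seq_len(cc)]], function(r) r$config)
    names(configs) <- ranked[seq_len(cc)]
    rep <- loocv(recordings, table, configs, score_name)
    data.frame(n_electrodes = cc, rho = rep$spearman$rho,
               accuracy = rep$classification$accuracy,
               auc = rep$classification$auc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("leapd_sweep", class(out))
  out
}

#' Recording-truncation robustness sweep
#'
#' Cuts every recording to the leading fraction of its samples (discarding
#' the end) and re-runs the full leave-one-out evaluation per fraction.
#'
#' @inheritParams loocv
#' @param fractions retained fractions in percent (default 10..100 step 5).
#' @return data.frame of class `leapd_sweep` with columns `fraction`,
#'   `rho`, `accuracy`, `auc`.
#' @export
truncation_sweep <- function(recordings, table, model_spec,
                             fractions = seq(10, 100, by = 5),
                             score_name = "moca") {
  configs <- spec_configs(model_spec)
  max_order <- max(vapply(configs, function(cfg) cfg$order, 0))
  rows <- lapply(fractions, function(fr) {
    recs <- lapply(recordings, truncate_recording, fraction = fr / 100)
    if (min(vapply(recs, n_samples, 0)) < 10 * max_order)
      stop(sprintf("truncation to %g%% leaves too few samples", fr))
    rep <- loocv(recs, table, configs, score_name)
    data.frame(fraction = fr, rho = rep$spearman$rho,
               accuracy = rep$classification$accuracy,
               auc = rep$classification$auc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("leapd_sweep", class(out))
  out
}
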