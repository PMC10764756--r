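#' Split subjects into cognitive training groups
#'
#' For MoCA the split uses the fixed clinical cutoff: impaired means
#' `moca < 26`, normal means `moca >= 26`. For the NIH-Toolbox scores the
#' cutoff is the median of the score over all included subjects: the low
#' group is `score < median`, the high group `score >= median` (so the
#' median subject lands in the high group). Subjects with a missing score
#' are excluded and reported.
#'
#' @param table subject data.frame (see [read_subject_table()]).
#' @param score_name one of `"moca"`, `"pvt"`, `"pcpst"`, `"dccst"`,
#'   `"ficat"`, `"psmt"`.
#' @param cutoff_rule `"fixed26"` (default for MoCA) or `"median"` (default
#'   otherwise).
#' @return list with `impaired` and `normal` id vectors (disjoint,
#'   exhaustive over included subjects), the numeric `cutoff`, and
#'   `excluded` ids with missing scores.
#' @export
split_groups <- function(table, score_name = "moca",
                         cutoff_rule = if (score_name == "moca") "fixed26" else "median") {
  score_name <- tolower(score_name)
  if (!score_name %in% names(table))
    stop(sprintf("subject table has no '%s' column", score_name))
  cutoff_rule <- match.arg(cutoff_rule, c("fixed26", "median"))
  score <- table[[score_name]]
  excluded <- table$id[is.na(score)]
  keep <- !is.na(score)
  ids <- table$id[keep]; score <- score[keep]
  cutoff <- if (cutoff_rule == "fixed26") 26 else stats::median(score)
  impaired <- ids[score < cutoff]
  normal <- ids[score >= cutoff]
  if (!length(impaired) || !length(normal))
    stop(sprintf("empty group after splitting on %s at cutoff %g",
                 score_name, cutoff))
  list(impaired = impaired, normal = normal, cutoff = cutoff,
       excluded = excluded)
}

#' Stratified subject-level cross-validation folds
#'
#' Shuffles subjects within each group (impaired / normal) under a fixed
#' seed and deals them round-robin into `k` folds, so every fold's training
#' complement retains members of both groups whenever group sizes allow.
#'
#' @param ids subject ids.
#' @param impaired logical vector (or ids subset) marking impaired subjects.
#' @param k number of folds, `2 <= k <= length(ids)`.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return named integer vector of fold numbers (1..k) per subject id.
#' @export
make_folds <- function(ids, impaired, k, seed) {
  if (!is.logical(impaired)) impaired <- ids %in% impaired
  k <- as.integer(k)
  if (k < 2 || k > length(ids))
    stop(sprintf("fold count %d invalid for %d subjects", k, length(ids)))
  set.seed(as.integer(seed))
  assign <- integer(length(ids)); names(assign) <- ids
  offset <- 0L
  for (grp in list(ids[impaired], ids[!impaired])) {
    if (!length(grp)) next
    shuffled <- sample(grp)
    assign[shuffled] <- ((seq_along(shuffled) - 1L + offset) %% k) + 1L
    offset <- offset + length(shuffled)
  }
  assign
}

# LPC coefficient matrix for one electrode and configuration: subjects in
# rows (rownames = ids), coefficients in columns. Recordings are expected to
# be preprocessed (normalized, notch-cleaned); the per-configuration
# bandpass is applied here.
lpc_matrix <- function(recordings, ids, electrode, band, order) {
  V <- matrix(NA_real_, nrow = length(ids), ncol = order,
              dimnames = list(ids, NULL))
  for (id in ids) {
    rec <- recordings[[id]]
    if (is.null(rec)) stop(sprintf("no recording for subject '%s'", id))
    x <- get_channel(rec, electrode)
    x <- bandpass(x, rec$fs, band)
    V[id, ] <- fit_lpc(x, order, fs = rec$fs)$coefficients
  }
  V
}

# Fit the impaired/normal subspace pair from an LPC matrix given group ids.
fit_pair <- function(V, impaired_ids, normal_ids, n) {
  subspace_pair(
    impaired = fit_affine_subspace(V[impaired_ids, , drop = FALSE], n),
    normal = fit_affine_subspace(V[normal_ids, , drop = FALSE], n))
}

# Out-of-fold indices given a precomputed LPC matrix, group membership and a
# fold assignment. Held-out subjects never contribute to the subspace fits.
oof_indices <- function(V, groups, fold_assign, n) {
  ids <- rownames(V)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (f in sort(unique(fold_assign))) {
    test_ids <- ids[fold_assign[ids] == f]
    train_ids <- setdiff(ids, test_ids)
    imp <- intersect(train_ids, groups$impaired)
    nor <- intersect(train_ids, groups$normal)
    if (!length(imp) || !length(nor))
      stop(sprintf("fold %d leaves an empty training group", f))
    pair <- fit_pair(V, imp, nor, n)
    for (id in test_ids) out[id] <- leapd_index(V[id, ], pair)
  }
  out
}

#' Out-of-fold single-electrode indices under cross-validation
#'
#' Partitions subjects into stratified folds at subject level, and for each
#' fold fits the group subspace pair on the remaining subjects only before
#' scoring the held-out subjects. Deterministic given the seed.
#'
#' @param recordings named list of preprocessed [eeg_recording()]s keyed by
#'   subject id.
#' @param table subject data.frame.
#' @param electrode channel label.
#' @param config list with `band` (`c(f_lo, f_hi)` Hz), `order` (LPC order
#'   `K`), `dim` (subspace dimension `n`).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param score_name score used to define the groups.
#' @return named numeric vector of out-of-fold indices per subject.
#' @export
single_electrode_index_cv <- function(recordings, table, electrode, config,
                                      folds = 10, seed = 1,
                                      score_name = "moca") {
  groups <- split_groups(table, score_name)
  ids <- c(groups$impaired, groups$normal)
  ids <- ids[ids %in% names(recordings)]
  V <- lpc_matrix(recordings, ids, electrode, config$band, config$order)
  fold_assign <- make_folds(ids, ids %in% groups$impaired,
                            min(folds, length(ids)), seed)
  oof_indices(V, groups, fold_assign, config$dim)
}

#' Parameter grid for the exhaustive search
#'
#' Enumerates bandpass ranges with integer Hz endpoints between `f_min` and
#' `f_max` (minimum bandwidth `min_bw`), LPC orders, and subspace dimensions
#' `1 .. K-1` (optionally capped).
#'
#' @param f_min,f_max outer frequency range in Hz (search domain 2-34 Hz).
#' @param min_bw minimum bandwidth in Hz.
#' @param step endpoint step in Hz.
#' @param orders LPC orders to search (2..10).
#' @param max_dim optional cap on the subspace dimension.
#' @return list of class `leapd_grid` with `bands` (two-column matrix),
#'   `orders`, `max_dim`.
#' @export
leapd_grid <- function(f_min = 2, f_max = 34, min_bw = 2, step = 1,
                       orders = 2:10, max_dim = Inf) {
  los <- seq(f_min, f_max - min_bw, by = step)
  bands <- do.call(rbind, lapply(los, function(lo) {
    his <- seq(lo + min_bw, f_max, by = step)
    cbind(lo, his)
  }))
  colnames(bands) <- c("f_lo", "f_hi")
  structure(list(bands = bands, orders = as.integer(orders),
                 max_dim = max_dim),
            class = "leapd_grid")
}

#' Compact parameter grid
#'
#' A small search grid for simulation studies and quick training runs: four
#' physiologically motivated passbands (broad 2-34 Hz, low 2-14 Hz,
#' theta-alpha 7-13 Hz, beta 13-26 Hz), LPC orders 5 and 7, and all
#' admissible subspace dimensions. The full integer-endpoint grid
#' ([leapd_grid()]) is the exhaustive counterpart.
#'
#' @return a `leapd_grid`.
#' @export
small_search_grid <- function() {
  g <- leapd_grid(orders = c(5L, 7L))
  g$bands <- rbind(c(2, 34), c(2, 14), c(7, 13), c(13, 26))
  colnames(g$bands) <- c("f_lo", "f_hi")
  g
}

#' Exhaustive per-electrode parameter search
#'
#' Scores every (band, order, dimension) configuration of the grid by the
#' Spearman rho between out-of-fold single-electrode indices and the
#' continuous cognitive score, under a single round of stratified k-fold
#' cross-validation (fold assignment fixed across configurations). Ties are
#' broken deterministically toward the narrower band, smaller order, smaller
#' dimension, then lower `f_lo`.
#'
#' @inheritParams single_electrode_index_cv
#' @param grid a [leapd_grid()].
#' @param store_grid if `TRUE`, the full grid score table is returned too.
#' @return list with `electrode`, `config` (best), `rho` (best
#'   cross-validated rho), and optionally `grid_scores`.
#' @export
grid_search_electrode <- function(recordings, table, electrode, grid,
                                  folds = 10, seed = 1, score_name = "moca",
                                  store_grid = FALSE) {
  if (!nrow(grid$bands)) stop("empty parameter grid")
  groups <- split_groups(table, score_name)
  ids <- c(groups$impaired, groups$normal)
  ids <- ids[ids %in% names(recordings)]
  score <- stats::setNames(table[[score_name]], table$id)[ids]
  fold_assign <- make_folds(ids, ids %in% groups$impaired,
                            min(folds, length(ids)), seed)
  # largest usable dimension: every fold's training groups must keep n+1 pts
  min_group <- min(vapply(sort(unique(fold_assign)), function(f) {
    train <- ids[fold_assign != f]
    min(sum(train %in% groups$impaired), sum(train %in% groups$normal))
  }, 0L))
  best <- NULL
  rows <- list()
  for (b in seq_len(nrow(grid$bands))) {
    band <- grid$bands[b, ]
    filtered <- lapply(ids, function(id) {
      rec <- recordings[[id]]
      bandpass(get_channel(rec, electrode), rec$fs, band)
    })
    names(filtered) <- ids
    fs <- recordings[[ids[1]]]$fs
    for (K in grid$orders) {
      V <- t(vapply(ids, function(id)
        fit_lpc(filtered[[id]], K, fs)$coefficients, numeric(K)))
      rownames(V) <- ids
      dims <- seq_len(min(K - 1, grid$max_dim, min_group - 1))
      for (n in dims) {
        idx <- oof_indices(V, groups, fold_assign, n)
        rho <- stats::cor(idx[ids], score, method = "spearman")
        cand <- list(band = as.numeric(band), order = K, dim = n, rho = rho)
        if (is.null(best) || better_config(cand, best)) best <- cand
        if (store_grid)
          rows[[length(rows) + 1L]] <- data.frame(
            f_lo = band[1], f_hi = band[2], order = K, dim = n, rho = rho)
      }
    }
  }
  if (is.null(best)) stop("no admissible configuration in the grid")
  out <- list(electrode = electrode,
              config = list(band = best$band, order = best$order,
                            dim = best$dim),
              rho = best$rho)
  if (store_grid) out$grid_scores <- do.call(rbind, rows)
  out
}

# Deterministic ordering: higher rho wins; ties toward narrower band,
# smaller order, smaller dimension, lower f_lo.
better_config <- function(cand, best) {
  if (is.na(cand$rho)) return(FALSE)
  if (is.na(best$rho)) return(TRUE)
  if (cand$rho != best$rho) return(cand$rho > best$rho)
  cw <- cand$band[2] - cand$band[1]; bw <- best$band[2] - best$band[1]
  if (cw != bw) return(cw < bw)
  if (cand$order != best$order) return(cand$order < best$order)
  if (cand$dim != best$dim) return(cand$dim < best$dim)
  cand$band[1] < best$band[1]
}

#' Run the grid search over several electrodes
#'
#' @inheritParams grid_search_electrode
#' @param electrodes channel labels to search; defaults to the channels of
#'   the first recording.
#' @return list of class `leapd_search`: per-electrode results (in input
#'   order), each as returned by [grid_search_electrode()].
#' @export
search_electrodes <- function(recordings, table, electrodes = NULL, grid,
                              folds = 10, seed = 1, score_name = "moca") {
  if (is.null(electrodes)) electrodes <- recordings[[1]]$channels
  res <- lapply(electrodes, function(el)
    grid_search_electrode(recordings, table, el, grid, folds, seed,
                          score_name))
  names(res) <- electrodes
  structure(res, class = "leapd_search")
}

#' Select the top-performing electrodes
#'
#' Ranks electrodes by their best cross-validated rho (descending) with a
#' stable tie-break by channel-list order, and returns the top `k` labels.
#'
#' @param results a `leapd_search` (list of per-electrode search results).
#' @param k number of electrodes to keep (default 8).
#' @return character vector of `k` electrode labels, best first.
#' @export
select_electrodes <- function(results, k = 8) {
  if (k < 1) stop("k must be at least 1")
  if (k > length(results))
    stop(sprintf("k = %d exceeds the %d searched electrodes", k,
                 length(results)))
  rhos <- vapply(results, function(r) r$rho, 0)
  ord <- order(-rhos, seq_along(rhos))
  names(results)[ord][seq_len(k)]
}

#' Fit the final LEAPD model
#'
#' Fits the per-electrode subspace pairs on all provided training subjects
#' using fixed, already-optimized configurations. The result is the
#' serializable trained model used for scoring and evaluation.
#'
#' @param recordings named list of preprocessed recordings.
#' @param table subject data.frame.
#' @param configs named list (by electrode label) of configurations, each
#'   with `band`, `order`, `dim`.
#' @param score_name cognitive score defining the groups.
#' @param notch_freqs line-noise frequencies recorded as preprocessing
#'   provenance.
#' @return object of class `leapd_model`.
#' @export
fit_model <- function(recordings, table, configs, score_name = "moca",
                      notch_freqs = c(60, 180, 200)) {
  groups <- split_groups(table, score_name)
  ids <- c(groups$impaired, groups$normal)
  ids <- ids[ids %in% names(recordings)]
  pairs <- list()
  for (el in names(configs)) {
    cfg <- configs[[el]]
    V <- lpc_matrix(recordings, ids, el, cfg$band, cfg$order)
    pairs[[el]] <- fit_pair(V, intersect(ids, groups$impaired),
                            intersect(ids, groups$normal), cfg$dim)
  }
  structure(
    list(score_name = score_name,
         cutoff_rule = if (score_name == "moca") "fixed26" else "median",
         cutoff = groups$cutoff,
         electrodes = names(configs), configs = configs, pairs = pairs,
         threshold = 0.5, fs = recordings[[ids[1]]]$fs,
         notch_freqs = notch_freqs),
    class = "leapd_model")
}

#' @export
print.leapd_model <- function(x, ...) {
  cat(sprintf("LEAPD model for %s (cutoff %g, threshold %g)\n",
              toupper(x$score_name), x$cutoff, x$threshold))
  for (el in x$electrodes) {
    cfg <- x$configs[[el]]
    cat(sprintf("  %-4s band %g-%g Hz, order %d, dim %d\n", el,
                cfg$band[1], cfg$band[2], cfg$order, cfg$dim))
  }
  invisible(x)
}

#' Score subjects with a fitted LEAPD model
#'
#' Computes the per-electrode and combined LEAPD indices for each recording
#' and the predicted label (index `< 0.5` means impaired).
#'
#' @param model a [fit_model()] result.
#' @param recordings named list of preprocessed recordings.
#' @return data.frame with `id`, one `rho_<electrode>` column per electrode,
#'   `combined`, `predicted`.
#' @export
score_subjects <- function(model, recordings) {
  ids <- names(recordings)
  per <- matrix(NA_real_, length(ids), length(model$electrodes),
                dimnames = list(ids, model$electrodes))
  for (el in model$electrodes) {
    cfg <- model$configs[[el]]
    for (id in ids) {
      rec <- recordings[[id]]
      if (!is.na(model$fs) && rec$fs != model$fs)
        stop(sprintf("sampling rate mismatch: model %g Hz, recording '%s' %g Hz",
                     model$fs, id, rec$fs))
      x <- bandpass(get_channel(rec, el), rec$fs, cfg$band)
      a <- fit_lpc(x, cfg$order, rec$fs)$coefficients
      per[id, el] <- leapd_index(a, model$pairs[[el]])
    }
  }
  combined <- apply(per, 1, combine_indices)
  out <- data.frame(id = ids, per, combined = combined,
                    predicted = ifelse(combined < model$threshold,
                                       "impaired", "normal"),
                    row.names = NULL, check.names = FALSE)
  names(out)[2:(1 + length(model$electrodes))] <-
    paste0("rho_", model$electrodes)
  out
}

subspace_to_list <- function(sub) {
  list(bias = sub$bias, basis = unclass(sub$basis), dim = sub$dim,
       n_train = sub$n_train)
}

subspace_from_list <- function(lst) {
  basis <- lst$basis
  if (!is.matrix(basis)) basis <- matrix(basis, ncol = lst$dim)
  structure(list(bias = as.numeric(lst$bias), basis = basis,
                 dim = as.integer(lst$dim), n_train = as.integer(lst$n_train)),
            class = "affine_subspace")
}

#' Serialize a LEAPD model to JSON
#'
#' Writes the full model (configurations, subspace pairs, preprocessing
#' provenance) as a single JSON document at full numeric precision, so a
#' reloaded model reproduces indices to machine precision.
#'
#' @param model a `leapd_model`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    score_name = model$score_name, cutoff_rule = model$cutoff_rule,
    cutoff = model$cutoff, electrodes = model$electrodes,
    configs = model$configs, threshold = model$threshold, fs = model$fs,
    notch_freqs = model$notch_freqs,
    pairs = lapply(model$pairs, function(p)
      list(impaired = subspace_to_list(p$impaired),
           normal = subspace_to_list(p$normal))))
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or file path from [model_to_json()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  pairs <- lapply(obj$pairs, function(p)
    subspace_pair(subspace_from_list(p$impaired),
                  subspace_from_list(p$normal)))
  configs <- lapply(obj$configs, function(cfg)
    list(band = as.numeric(cfg$band), order = as.integer(cfg$order),
         dim = as.integer(cfg$dim)))
  structure(
    list(score_name = obj$score_name, cutoff_rule = obj$cutoff_rule,
         cutoff = obj$cutoff, electrodes = unlist(obj$electrodes),
         configs = configs, pairs = pairs, threshold = obj$threshold,
         fs = obj$fs, notch_freqs = unlist(obj$notch_freqs)),
    class = "leapd_model")
}
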