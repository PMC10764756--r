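# Shared 20-seed simulation sweep used by the synthetic-recovery,
# randomization-null and truncation acceptance tests. Computed lazily once
# per session and cached, since the three checks share the same cohorts and
# fitted configurations.

.criteria_cache <- new.env(parent = emptyenv())

criteria_sweep <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.criteria_cache[[key]])) return(.criteria_cache[[key]])
  rows <- lapply(seeds, function(seed) {
    coh <- generate_cohort(cohort_spec(
      n_subjects = 120, duration = 20,
      electrodes = c("P8", "PO7", "CP1", "CP2", "O2"),
      informative = c("P8", "PO7", "CP1", "CP2"), seed = seed))
    recs <- lapply(coh$recordings, preprocess_recording)
    search <- search_electrodes(recs, coh$table,
                                c("P8", "PO7", "CP1", "CP2"),
                                small_search_grid(), folds = 10, seed = seed)
    configs <- lapply(search, function(r) r$config)
    rep_full <- loocv(recs, coh$table, configs)
    latent <- coh$table$latent[match(names(rep_full$indices), coh$table$id)]
    shuf <- randomization_test(recs, coh$table, configs, seed = seed)
    rep10 <- loocv(lapply(recs, truncate_recording, fraction = 0.1),
                   coh$table, configs)
    data.frame(
      seed = seed,
      rho_latent = stats::cor(rep_full$indices, latent, method = "spearman"),
      auc = rep_full$classification$auc,
      accuracy = rep_full$classification$accuracy,
      null_rho = shuf$spearman$rho,
      null_auc = shuf$classification$auc,
      auc_trunc10 = rep10$classification$auc)
  })
  out <- do.call(rbind, rows)
  .criteria_cache[[key]] <- out
  out
}
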