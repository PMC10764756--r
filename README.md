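# leapd

EEG-based cognitive indexing via linear predictive coding and
affine-subspace geometry.

## What problem this solves

Cognitive impairment — in Parkinson's disease especially — is usually
quantified with screening instruments such as the MoCA, which need a
trained examiner and are insensitive to short-term fluctuation. A few
minutes of resting-state EEG carry cognition-related changes spread across
the whole power spectrum (theta–alpha peak shifts, beta amplitude changes),
not confined to any one canonical band. `leapd` implements LEAPD, a
data-driven index that captures those broad-spectrum changes and maps a
recording to a single number in [0, 1] that tracks cognitive function.

The package is for methodologists and clinical-neurophysiology researchers
who want to train, evaluate, or stress-test this class of index — on their
own recordings (BrainVision, EDF, or plain numeric matrices) or on fully
synthetic cohorts that need no data download.

## The method

For each selected electrode, the (energy-normalized, notch-cleaned,
bandpassed) channel is encoded by order-*K* linear predictive coding:

    x(n) = eps(n) - sum_{i=1..K} a_i x(n - i)

The coefficient vector **a** is one point in R^K that compresses the
channel's spectral shape. Cognitively impaired and cognitively normal
training groups each define an affine subspace in that space (group mean +
top-*n* right-singular vectors of the centered, 1/sqrt(S-1)-scaled
coefficient matrix). A new recording is scored by its distances D_imp,
D_norm to the two subspaces:

    rho = D_imp / (D_imp + D_norm)

so rho = 1 on the normal subspace, 0 on the impaired one, and rho < 0.5
flags impairment. Per-electrode indices combine by geometric mean. The
band, order *K*, and dimension *n* are tuned per electrode by exhaustive
search maximizing the Spearman correlation between out-of-fold indices and
the continuous cognitive score under stratified 10-fold cross-validation;
electrodes are then ranked by that correlation and the top *k* feed the
combined index.

The evaluation harness covers leave-one-out and repeated k-fold
cross-validation, label-shuffling randomization tests, age-adjusted partial
Spearman correlations, classification metrics (accuracy, AUC, sensitivity,
specificity, PPV/NPV, odds ratio), linear/quadratic regressions with AIC
and likelihood-ratio comparison, and robustness sweeps over electrode count
and recording truncation. Canonical band powers and the alpha/theta
log-ratio are included as traditional baselines.

## Worked example

Train and score on a small synthetic cohort (12 subjects, 2 electrodes of
which one carries the cognition-linked oscillations, 20 s of "EEG" each):

```r
library(leapd)

cohort <- generate_cohort(cohort_spec(
  n_subjects = 12, electrodes = c("P8", "PO7"), informative = "P8",
  duration = 20, scores = c(9, 11, 14, 16, 19, 21, 23, 24, 26, 27, 29, 30),
  seed = 42))
recs <- lapply(cohort$recordings, preprocess_recording)

grid <- leapd_grid(orders = c(4L, 6L))
grid$bands <- rbind(c(5, 15), c(2, 34))
search <- search_electrodes(recs, cohort$table, c("P8", "PO7"), grid,
                            folds = 4, seed = 1)
model <- fit_model(recs, cohort$table, lapply(search, function(r) r$config))
print(model)
out <- score_subjects(model, recs)
out$moca <- cohort$table$moca
out[, c("id", "moca", "combined", "predicted")]
loocv(recs, cohort$table, model)
```

```
LEAPD model for MOCA (cutoff 26, threshold 0.5)
  P8   band 5-15 Hz, order 4, dim 2
  PO7  band 2-34 Hz, order 4, dim 1
     id moca   combined predicted
1  S001    9 0.26694456  impaired
2  S002   11 0.13260979  impaired
3  S003   14 0.06751429  impaired
4  S004   16 0.09140108  impaired
5  S005   19 0.51328319    normal
6  S006   21 0.17096989  impaired
7  S007   23 0.29301829  impaired
8  S008   24 0.20245122  impaired
9  S009   26 0.68978480    normal
10 S010   27 0.82221206    normal
11 S011   29 0.81743188    normal
12 S012   30 0.75803357    normal
LEAPD evaluation (loocv, MOCA, n = 12)
  age-adjusted Spearman rho = 0.523 (p = 0.0991)
  accuracy 83.33%, AUC 0.906, sens 87.50%, spec 75.00%
  linear R2 0.327 (RMSE 0.262 scaled), quadratic R2 0.327, LRT p 0.985
```

The per-electrode search picked a theta–alpha band (5–15 Hz) with a
2-dimensional subspace pair for the informative electrode P8 and a broad
band for the uninformative PO7. On training data 11 of 12 subjects land on
the correct side of 0.5 (one borderline at 0.513); the leave-one-out
report shows what survives out of sample at this tiny cohort size
(AUC 0.91, accuracy 83%). `kfold_cv()` and `randomization_test()` probe
the same pipeline with repeated shuffled folds and with destroyed labels.
At the simulation-study size (120 subjects, 4 informative electrodes) the
LOOCV Spearman rho is typically around 0.8 — see the acceptance script
below. An even smaller fixed 8-subject fixture for fast smoke tests is
available as `generate_worked_example()`.

A larger simulation — 120 subjects, 4 informative electrodes, parameter
search and leave-one-out evaluation — is exactly what the acceptance
script runs (below). A command-line interface wrapping the same functions
lives at `inst/cli/leapd.R`:

```sh
Rscript inst/cli/leapd.R simulate --out cohort/ --seed 3 --n 20 --duration 30
Rscript inst/cli/leapd.R train    --data cohort/ --out model.json --grid small --seed 3
Rscript inst/cli/leapd.R score    --data cohort/ --model model.json --out scores.csv
Rscript inst/cli/leapd.R evaluate --data cohort/ --model model.json --scheme loocv --out eval.json
```

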