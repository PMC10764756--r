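---
title: "LEAPD: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LEAPD: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapd)
```

## The model

LEAPD scores cognition from resting-state EEG in three steps.

**1. LPC encoding.** Each (preprocessed, bandpassed) EEG channel is fitted
with an order-$K$ autoregressive model,

$$x(n) = \epsilon(n) - \sum_{i=1}^{K} a_i\, x(n-i),$$

by the autocorrelation method solved with the Levinson–Durbin recursion
(`fit_lpc()`). The coefficient vector $\mathbf a = [a_1,\dots,a_K]^T$
compresses the channel's spectral shape: the implied all-pole density is
$\sigma^2 / |A(e^{j2\pi f/f_s})|^2$ with $A(z) = 1 + \sum_i a_i z^{-i}$
(`lpc_spectrum()`), and the complex pole pairs of $A$ are the signal's
oscillatory modes (`oscillatory_modes()`). The autocorrelation method
guarantees a stable model, so pole magnitudes never exceed 1. We fit one
model per channel on the whole continuous recording — no windowing or
segment averaging — because the score is meant to summarize the recording
as a single point in coefficient space.

**2. Affine-subspace geometry.** The training cohort is split into
cognitively impaired and cognitively normal groups. Each group's LPC
vectors are centered on their mean $\mathbf m_c$ and scaled by
$1/\sqrt{S-1}$; the first $n$ right-singular vectors of that matrix form an
orthonormal basis $\mathbf p_{c,1},\dots,\mathbf p_{c,n}$
(`fit_affine_subspace()`). The distance from a new coefficient vector
$\mathbf a$ to a group subspace is the norm of the component of
$\mathbf a - \mathbf m_c$ orthogonal to the basis span
(`subspace_distance()`). The $1/\sqrt{S-1}$ scaling changes singular values
only, never the basis or any distance; it is kept because it makes the
singular values interpretable as per-direction standard deviations.

**3. The index.** With $D_{\mathrm{imp}}$ and $D_{\mathrm{norm}}$ the two
distances, the single-electrode index is

$$\rho = \frac{D_{\mathrm{imp}}}{D_{\mathrm{imp}} + D_{\mathrm{norm}}} \in [0,1],$$

so $\rho = 0$ on the impaired subspace, $\rho = 1$ on the normal subspace,
and $\rho < 0.5$ means impaired-like (`leapd_index()`). Indices from $L$
electrodes combine by geometric mean (`combine_indices()`). A point lying
in both subspaces has no preferred side; it is scored 0.5 with a warning.

**Orientation.** Descriptions of distance-ratio indices of this kind are
not always consistent about which distance sits in the numerator. We fix
the orientation once: *high index = normal cognition*, so the decision
rule (index $< 0.5$ flags impairment) reads naturally, and note that
swapping the two subspaces maps $\rho \mapsto 1-\rho$ exactly.

## Preprocessing

Fixed, per recording (`preprocess_recording()`):

1. **Energy normalization** — each channel is divided by the square root of
   its total energy, removing amplitude-scale differences between channels
   and subjects. LPC coefficients are themselves scale-invariant; the
   normalization additionally fixes the scale of the residual variance.
2. **Line-noise removal** — FFT bins within ±0.5 Hz of 60, 180 and 200 Hz
   (and their mirrored bins) are zeroed and the transform inverted
   (`remove_line_noise()`). Bin-zeroing is the simplest frequency-domain
   notch; its leakage outside ±1 Hz is below 1% of band power.
   The order (normalize, then notch) is a documented convention; the two
   operations nearly commute because the line components carry a small
   fraction of total energy.
3. **Bandpass at scoring time** — a zero-phase 6th-order Butterworth
   bandpass (`bandpass()`; 3rd-order prototype applied forward and
   backward) selects the per-electrode frequency range, which is a tuned
   model parameter rather than a fixed preprocessing constant. Edges are
   odd-reflection padded by $3\times(\text{order}+1)$ samples, the standard
   zero-phase convention, to suppress startup transients.

No artifact rejection, re-referencing, epoching or resampling is applied:
the method is intended to run on whole continuous recordings exactly as
acquired.

## Training protocol

* **Group construction** (`split_groups()`): MoCA uses the fixed clinical
  cutoff 26 (impaired $<$ 26). NIH-Toolbox scores use the cohort median,
  with the median subject assigned to the high group — a convention chosen
  so the rule is deterministic for odd cohorts.
* **Parameter search** (`grid_search_electrode()`): for each electrode, an
  exhaustive search over bandpass range, LPC order $K \in 2..10$ and
  subspace dimension $n \in 1..K-1$, scored by the Spearman correlation
  between out-of-fold indices and the continuous cognitive score under a
  single round of stratified 10-fold cross-validation. The full grid
  (`leapd_grid()`) uses integer Hz endpoints in 2–34 Hz with minimum
  bandwidth 2 Hz (~500 bands); the endpoint step is configurable because
  nothing in the method depends on the grid being dense. Ties break
  deterministically toward the narrower band, smaller $K$, smaller $n$,
  lower low edge, making the search invariant to enumeration order.
* **Electrode selection** (`select_electrodes()`): electrodes ranked by
  their best cross-validated rho; the top $k$ (default 8) feed the combined
  index. The ranking reuses the grid-search CV scores rather than running a
  second CV pass.
* **Final fit** (`fit_model()`): subspace pairs refitted on *all* training
  subjects with the selected configurations, which are then held fixed for
  every evaluation.
* **Folds** (`make_folds()`): subject-level, shuffled under an explicit
  seed, stratified by group so no training split loses a group entirely.
  A training split must still retain at least $n+1$ subjects per group to
  span an $n$-dimensional subspace; configurations violating this for any
  fold are inadmissible and skipped.

## Evaluation harness

`loocv()` refits the subspace pairs without each subject in turn
(configurations fixed), `kfold_cv()` repeats stratified $k$-fold splits
over independent shuffling rounds, and `randomization_test()` permutes the
cognitive scores once (seeded) before re-running the full leave-one-out
pipeline — groups are re-split from the shuffled scores, so the null run
retrains everything except the fixed configurations.

Metrics: age-adjusted partial Spearman correlation
(`partial_spearman()`: rank-transform all variables, adjust the two rank
vectors linearly for the covariate ranks, correlate residuals; two-sided
p from the t approximation with $n-2-\#\text{covariates}$ df);
classification at the fixed 0.5 threshold with impaired as the positive
class, an index of exactly 0.5 read as normal (strict inequality), AUC as
the Mann–Whitney rank statistic with impaired as the low-index class, and
a Haldane–Anscombe 0.5 correction (flagged) for odds ratios with empty
cells; linear and quadratic regressions of score on index with $R^2$,
F tests against the intercept-only model, Gaussian AIC
$n\ln(\mathrm{RSS}/n) + 2(p+1)$ and a $\chi^2(1)$ likelihood-ratio test of
quadratic vs linear. RMSE is reported twice — on the raw score scale and
with both variables min–max scaled to $[0,1]$ — because the scale
convention behind published RMSE values of this kind is ambiguous;
emitting both avoids committing to either.

Age adjustment applies to correlation metrics only, never to
classification. Robustness sweeps re-run the LOOCV while varying the
number of top-ranked electrodes (`electrode_sweep()`) or cutting every
recording to its leading fraction, discarding the end
(`truncation_sweep()`, `truncate_recording()` keeps
$\lceil \text{fraction}\times N\rceil$ samples).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the index assumes,
not biophysical EEG. Per subject, a latent cognition score is drawn
uniformly on 9–30 (treated as MoCA after rounding). On informative
electrodes the signal is the sum of

* a **theta–alpha AR(2) resonator** whose center frequency rises linearly
  from 7 Hz to 13 Hz across the score range (slope 6/21 Hz per score
  unit), pole magnitude 0.95, unit component sd;
* a **beta resonator** at 20 Hz, pole magnitude 0.90, whose amplitude
  rises linearly from 0.35 to 1.0 across the score range;
* a **1/f background** (spectrally shaped white noise, exponent 1, sd 1),
  a **60 Hz line** sinusoid (amplitude 0.5) and **white noise** (sd 0.5).

Uninformative electrodes carry the background plus a fixed 10 Hz alpha
rhythm, so they look EEG-like but carry no score information. Ages are
normal (mean 68.5, sd 8). The slopes' direction (frequency and amplitude
both increasing with the score) mirrors the oscillatory-mode shifts the
method is designed to exploit; since the published regressions relate
score to mode parameters without fixing a generative direction, the
generator parameterizes the generative direction explicitly. Defaults are
500 Hz sampling and 160 s recordings, matching typical resting-state
acquisitions of a few minutes.

What passing simulation tests show: that the full pipeline — encoding,
geometry, search, cross-validation — recovers a monotone spectral-shape
signal of realistic size from realistic noise, and finds nothing when the
signal is destroyed by label shuffling. What they do not show: performance
on real EEG, which contains artifacts, nonstationarity, volume-conduction
correlations between channels and score distributions far from uniform.

RNG: all stochastic steps (cohort generation, fold shuffles, score
permutations) run under R's default Mersenne-Twister with an explicit
integer seed recorded in every artifact; R's RNG is platform-deterministic,
so seeded outputs are bit-reproducible across machines.

## Numerical choices

* Levinson–Durbin uses biased sample autocorrelations $r(k) = N^{-1}\sum
  x(n)x(n+k)$; fits reject constant signals and require $N \ge 10K$.
* Singular values below $10^{-12}$ of the largest are treated as zero;
  a subspace request exceeding the numeric rank is truncated with a
  warning rather than inverted through noise.
* The projection in the distance formula divides by
  $\mathbf p^T\mathbf p$ even though the basis is orthonormal, keeping the
  implementation literal to the estimator's definition at no cost.
* Welch band powers use 2 s Hann windows with 50% overlap, one-sided
  density scaling; the estimator choice is a documented convention. The
  alpha/theta ratio uses $\log_{10}$ (configurable).
* Mode "amplitude" is defined as the model spectral density at the pole
  frequency — monotone in both residue size and pole sharpness. This is
  one consistent reading of an a.u. amplitude axis, not the only one.
* The spectral *maximum* of a damped AR(2) resonator sits slightly below
  its pole frequency (9.1 Hz for a 10 Hz pole at magnitude 0.95 and
  500 Hz sampling); mode frequencies are therefore reported from pole
  angles, not from spectral peaks.

## Problem sizes used in the shipped checks

The simulation studies in the test suite and the acceptance script use
cohorts of $n = 120$ subjects, 5 electrodes (4 informative), 20 s
recordings at 500 Hz, a compact search grid (`small_search_grid()`: four
physiologically motivated bands × orders {5, 7} × all admissible
dimensions) and 20-seed sweeps. These sizes are the package's choice of a
desk-scale study; recordings of a few minutes and the exhaustive grid
behave the same way, only slower. Under these conditions the pipeline
typically reaches LOOCV Spearman rho ≈ 0.8 against the latent score and
AUC ≈ 0.95–1.0 for detecting the impaired group, with null runs at
|rho| ≲ 0.1 and AUC ≈ 0.5 — the tests assert the thresholds, not these
typical values.

## Limitations

* The affine-subspace model is linear in coefficient space; strongly
  nonlinear group manifolds would need kernelized extensions (out of
  scope).
* Exactly two groups are supported; multi-class extensions are not.
* The readers for BrainVision and EDF cover the common single-record
  layouts (multiplexed/vectorized, float-32/int-16/ASCII; uniform
  samples-per-record EDF) and are not general-purpose EEG I/O.
* No artifact handling is provided by design; heavily contaminated
  recordings will degrade the encoding silently.
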