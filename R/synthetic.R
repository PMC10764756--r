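#' Specification for a synthetic EEG cohort
#'
#' Describes a cohort whose statistical structure mirrors what the LEAPD
#' index assumes: on informative electrodes, a theta-alpha oscillation whose
#' frequency rises linearly with a latent cognition score, and a beta
#' oscillation whose amplitude rises with the score, superimposed on a 1/f
#' background with 60 Hz line contamination and white sensor noise.
#' Uninformative electrodes carry the background plus a fixed 10 Hz alpha
#' rhythm that does not depend on the score.
#'
#' Defaults: 500 Hz sampling, 160 s recordings, latent scores uniform on
#' 9-30 (treated as MoCA), theta-alpha frequency spanning 7-13 Hz over the
#' score range, ages normal with mean 68.5 and sd 8.
#'
#' @param n_subjects cohort size.
#' @param electrodes channel labels.
#' @param informative labels of the score-dependent electrodes.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param score_range latent cognition score range `c(lo, hi)`.
#' @param ta_base_freq theta-alpha frequency in Hz at the low end of the
#'   score range.
#' @param ta_freq_slope theta-alpha frequency increase in Hz per score unit.
#' @param ta_amp theta-alpha oscillation amplitude (component sd).
#' @param ta_pole theta-alpha pole magnitude in (0, 1).
#' @param beta_freq beta oscillation frequency in Hz.
#' @param beta_pole beta pole magnitude in (0, 1).
#' @param beta_base_amp beta amplitude (component sd) at the low score end.
#' @param beta_amp_slope beta amplitude increase per score unit.
#' @param pink_level 1/f background amplitude (component sd).
#' @param pink_exponent 1/f spectral exponent.
#' @param line_amp 60 Hz line-noise sinusoid amplitude.
#' @param noise_sd white sensor-noise sd.
#' @param age_mean,age_sd age distribution parameters (years).
#' @param scores optional fixed latent scores (overrides the uniform draw).
#' @param seed integer seed; fully determines the cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120,
                        electrodes = c("P8", "PO7", "CP1", "CP2", "O2", "F4"),
                        informative = c("P8", "PO7", "CP1", "CP2"),
                        fs = 500, duration = 160,
                        score_range = c(9, 30),
                        ta_base_freq = 7, ta_freq_slope = 6 / 21,
                        ta_amp = 1, ta_pole = 0.95,
                        beta_freq = 20, beta_pole = 0.90,
                        beta_base_amp = 0.35, beta_amp_slope = 0.65 / 21,
                        pink_level = 1, pink_exponent = 1,
                        line_amp = 0.5, noise_sd = 0.5,
                        age_mean = 68.5, age_sd = 8,
                        scores = NULL, seed = 1) {
  spec <- list(n_subjects = n_subjects, electrodes = electrodes,
               informative = informative, fs = fs, duration = duration,
               score_range = score_range, ta_base_freq = ta_base_freq,
               ta_freq_slope = ta_freq_slope, ta_amp = ta_amp,
               ta_pole = ta_pole, beta_freq = beta_freq,
               beta_pole = beta_pole, beta_base_amp = beta_base_amp,
               beta_amp_slope = beta_amp_slope, pink_level = pink_level,
               pink_exponent = pink_exponent, line_amp = line_amp,
               noise_sd = noise_sd, age_mean = age_mean, age_sd = age_sd,
               scores = scores, seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2) stop("cohort needs at least 2 subjects")
  if (!all(spec$informative %in% spec$electrodes))
    stop("informative electrodes must be among the electrode labels")
  for (p in c(spec$ta_pole, spec$beta_pole))
    if (p <= 0 || p >= 1) stop("pole magnitudes must lie in (0, 1)")
  if (!all(is.finite(c(spec$ta_freq_slope, spec$beta_amp_slope))))
    stop("slopes must be finite")
  if (spec$duration * spec$fs < 100)
    stop("recordings too short for the maximum LPC order")
  if (!is.null(spec$scores) && length(spec$scores) != spec$n_subjects)
    stop("fixed scores must have one value per subject")
  invisible(spec)
}

# AR(2) resonator: white noise through poles at r * exp(+/- i 2 pi f / fs),
# output normalized to unit sd then scaled.
resonator <- function(n, fs, freq, pole, amp) {
  e <- stats::rnorm(n)
  theta <- 2 * pi * freq / fs
  y <- as.numeric(stats::filter(e, c(2 * pole * cos(theta), -pole^2),
                                method = "recursive"))
  amp * y / stats::sd(y)
}

# 1/f background by spectral shaping of white noise.
pink_noise <- function(n, exponent, amp) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric shaping keeps the output real
  X <- X / f^(exponent / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  amp * y / stats::sd(y)
}

#' Generate a synthetic EEG cohort
#'
#' Draws per-subject latent cognition scores and synthesizes per-electrode
#' EEG per the spec: informative electrodes carry the score-linked
#' theta-alpha and beta oscillations, uninformative electrodes only the
#' score-free background. Output is bit-reproducible given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `recordings` (named list of
#'   [eeg_recording()]s), `table` (subject data.frame; the latent score is
#'   rounded into a MoCA column), and `truth` (per-subject true mode
#'   frequencies and amplitudes).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(as.integer(spec$seed))
  n <- spec$n_subjects
  nsamp <- round(spec$duration * spec$fs)
  ids <- sprintf("S%03d", seq_len(n))
  score <- if (!is.null(spec$scores)) as.numeric(spec$scores)
           else stats::runif(n, spec$score_range[1], spec$score_range[2])
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  group <- sample(c("PD", "control"), n, replace = TRUE, prob = c(2, 1))
  t_sec <- (seq_len(nsamp) - 1) / spec$fs
  line <- spec$line_amp * sin(2 * pi * 60 * t_sec)
  recordings <- vector("list", n); names(recordings) <- ids
  ta_freq <- spec$ta_base_freq +
    spec$ta_freq_slope * (score - spec$score_range[1])
  beta_amp <- spec$beta_base_amp +
    spec$beta_amp_slope * (score - spec$score_range[1])
  for (i in seq_len(n)) {
    dat <- matrix(0, nsamp, length(spec$electrodes))
    for (j in seq_along(spec$electrodes)) {
      bg <- pink_noise(nsamp, spec$pink_exponent, spec$pink_level) +
        line + spec$noise_sd * stats::rnorm(nsamp)
      if (spec$electrodes[j] %in% spec$informative) {
        dat[, j] <- bg +
          resonator(nsamp, spec$fs, ta_freq[i], spec$ta_pole, spec$ta_amp) +
          resonator(nsamp, spec$fs, spec$beta_freq, spec$beta_pole,
                    beta_amp[i])
      } else {
        dat[, j] <- bg + resonator(nsamp, spec$fs, 10, spec$ta_pole, 1)
      }
    }
    recordings[[i]] <- eeg_recording(dat, spec$fs, spec$electrodes, ids[i])
  }
  table <- data.frame(
    id = ids, age = round(age, 1), sex = sex, group = group,
    moca = pmin(30, pmax(0, round(score))),
    latent = score, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, ta_frequency = ta_freq,
                      beta_amplitude = beta_amp, latent = score)
  structure(list(recordings = recordings, table = table, truth = truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic EEG cohort: %d subjects, %d electrodes (%d informative), %g s @ %g Hz, seed %d\n",
    x$spec$n_subjects, length(x$spec$electrodes),
    length(x$spec$informative), x$spec$duration, x$spec$fs, x$spec$seed))
  invisible(x)
}

#' Small fixed worked-example cohort
#'
#' An 8-subject, 2-electrode, 10-second cohort with a hard-coded seed and
#' fixed latent scores spanning the MoCA range (5 impaired, 3 normal), small
#' enough for fast unit tests and worked examples while keeping every
#' stratified training split able to span both group subspaces.
#'
#' @return a `synthetic_cohort`.
#' @export
generate_worked_example <- function() {
  generate_cohort(cohort_spec(
    n_subjects = 8, electrodes = c("P8", "PO7"), informative = "P8",
    duration = 10, scores = c(9, 13, 17, 21, 24, 26, 28, 30), seed = 42))
}

#' Write a synthetic cohort to disk in the matrix dialect
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing); one CSV + JSON sidecar
#'   per subject plus `subjects.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings))
    write_matrix_recording(cohort$recordings[[id]],
                           file.path(dir, paste0(id, ".csv")))
  utils::write.csv(cohort$table, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}
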