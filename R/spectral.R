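#' Canonical EEG frequency bands
#'
#' The five canonical rhythms: delta (1-4 Hz), theta (4-8 Hz), alpha
#' (8-13 Hz), beta (13-30 Hz), gamma (31-100 Hz).
#'
#' @return named list of `c(f_lo, f_hi)` ranges in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(31, 100))
}

#' Welch power spectral density estimate
#'
#' Mean periodogram over Hann-windowed segments (default 2-second windows,
#' 50% overlap), scaled as a one-sided density so that the integral over
#' `[0, fs/2]` estimates the signal's mean power.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_seconds segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_seconds * fs))
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))  # Hann
  U <- sum(w^2)
  nf <- nseg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  scale <- rep(2, nf); scale[1] <- 1
  if (nseg %% 2 == 0) scale[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / nseg, psd = psd * scale)
}

#' Band power from the Welch estimate
#'
#' Integrates the Welch power spectral density over `[f_lo, f_hi)`.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band `c(f_lo, f_hi)` in Hz with `f_hi < fs/2` (the gamma band
#'   requires `fs > 200`).
#' @param ... passed to [welch_psd()].
#' @return nonnegative scalar power (a.u.).
#' @export
band_power <- function(x, fs, band, ...) {
  band <- as.numeric(band)
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  if (band[1] >= band[2]) stop("invalid band")
  est <- welch_psd(x, fs, ...)
  df <- est$freq[2] - est$freq[1]
  sel <- est$freq >= band[1] & est$freq < band[2]
  sum(est$psd[sel]) * df
}

#' Alpha/theta log-ratio
#'
#' `log10` of the ratio of alpha (8-13 Hz) to theta (4-8 Hz) band power; a
#' classical marker that rises when the dominant rhythm shifts from theta
#' into alpha. The log base is a documented convention (base 10).
#'
#' @inheritParams band_power
#' @param base logarithm base (default 10).
#' @return scalar log-ratio.
#' @export
alpha_theta_log_ratio <- function(x, fs, base = 10, ...) {
  a <- band_power(x, fs, canonical_bands()$alpha, ...)
  t <- band_power(x, fs, canonical_bands()$theta, ...)
  if (t <= 0) stop("zero theta-band power")
  log(a / t, base = base)
}

#' Age-adjusted correlation topography
#'
#' Per-electrode age-adjusted partial Spearman correlation between a
#' spectral feature and a cognitive score, flagged at uncorrected
#' `p < 0.05`.
#'
#' @param features numeric matrix, subjects x electrodes (column names are
#'   electrode labels).
#' @param scores numeric vector of cognitive scores, one per subject.
#' @param ages numeric vector of ages, one per subject.
#' @return data.frame with columns `electrode`, `rho`, `p`, `significant`.
#' @export
correlation_topography <- function(features, scores, ages) {
  features <- as.matrix(features)
  if (nrow(features) != length(scores) || length(scores) != length(ages))
    stop("features, scores and ages must cover the same subjects")
  rows <- lapply(seq_len(ncol(features)), function(j) {
    sp <- partial_spearman(features[, j], scores, covariates = ages)
    data.frame(electrode = colnames(features)[j] %||% as.character(j),
               rho = sp$rho, p = sp$p, significant = sp$p < 0.05)
  })
  do.call(rbind, rows)
}

#' Spectral feature matrix for a cohort
#'
#' Computes the canonical band powers (and the alpha/theta log-ratio) for
#' every subject and electrode, the traditional comparators to the LEAPD
#' index.
#'
#' @param recordings named list of [eeg_recording()]s.
#' @param bands named list of bands (default [canonical_bands()]); bands at
#'   or above Nyquist are skipped.
#' @return list of matrices (subjects x electrodes), one per band, plus
#'   `alpha_theta_ratio`.
#' @export
spectral_features <- function(recordings, bands = canonical_bands()) {
  ids <- names(recordings)
  chans <- recordings[[1]]$channels
  fs <- recordings[[1]]$fs
  bands <- bands[vapply(bands, function(b) b[2] < fs / 2, TRUE)]
  out <- lapply(bands, function(b) {
    m <- matrix(NA_real_, length(ids), length(chans),
                dimnames = list(ids, chans))
    for (id in ids) for (ch in chans)
      m[id, ch] <- band_power(get_channel(recordings[[id]], ch), fs, b)
    m
  })
  ratio <- matrix(NA_real_, length(ids), length(chans),
                  dimnames = list(ids, chans))
  for (id in ids) for (ch in chans)
    ratio[id, ch] <- alpha_theta_log_ratio(get_channel(recordings[[id]], ch),
                                           fs)
  out$alpha_theta_ratio <- ratio
  out
}
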