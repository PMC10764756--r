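#' Normalize a signal to unit total energy
#'
#' Divides a time series by the square root of its total energy (the sum of
#' squared samples), so that every channel carries the same amplitude scale
#' into the LPC encoding.
#'
#' @param x numeric vector, not identically zero.
#' @return numeric vector of the same length with `sum(x^2) == 1`.
#' @export
normalize_energy <- function(x) {
  e <- sum(x^2)
  if (e == 0) stop("cannot normalize an all-zero signal (degenerate channel)")
  x / sqrt(e)
}

#' Remove line-noise components in the frequency domain
#'
#' Zeroes the FFT bins within +/- 0.5 Hz of each target frequency (and the
#' mirrored negative-frequency bins, keeping the output real) and inverts the
#' transform. Used to strip 60 Hz mains interference and its contaminated
#' 180 / 200 Hz components.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param freqs frequencies to remove, each strictly below `fs / 2`.
#' @param halfwidth half-width of the removal window in Hz (default 0.5).
#' @return numeric vector, same length as `x`.
#' @export
remove_line_noise <- function(x, fs, freqs = c(60, 180, 200),
                              halfwidth = 0.5) {
  if (any(freqs >= fs / 2))
    stop("line-noise target frequency at or above Nyquist")
  n <- length(x)
  X <- stats::fft(x)
  bin_freq <- (seq_len(n) - 1) * fs / n
  # fold to [0, fs/2] so negative-frequency bins mirror automatically
  folded <- pmin(bin_freq, fs - bin_freq)
  kill <- rep(FALSE, n)
  for (f in freqs)
    kill <- kill | (abs(folded - f) <= halfwidth)
  X[kill] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Design and apply a zero-phase Butterworth bandpass
#'
#' Applies a 6th-order Butterworth bandpass (a 3rd-order prototype, giving a
#' 6-pole transfer function) forward and backward so the net phase shift is
#' zero. Edges are odd-reflection padded by `3 * (order + 1)` samples to
#' suppress startup transients.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2 vector `c(f_lo, f_hi)` in Hz,
#'   `0 < f_lo < f_hi < fs/2`.
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, band) {
  band <- validate_band(band, fs)
  bt <- butter_cached(band, fs)
  filtfilt_padded(bt$b, bt$a, x)
}

# filter designs are deterministic in (band, fs); cache them, the parameter
# search revisits the same bands for every subject
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(band, fs) {
  key <- paste(band[1], band[2], fs, sep = "|")
  bt <- .butter_cache[[key]]
  if (is.null(bt)) {
    bt <- signal::butter(3, c(band[1], band[2]) / (fs / 2), type = "pass")
    .butter_cache[[key]] <- bt
  }
  bt
}

validate_band <- function(band, fs) {
  band <- as.numeric(band)
  if (length(band) != 2L || !all(is.finite(band)))
    stop("band must be c(f_lo, f_hi)")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop(sprintf("invalid band (%g, %g) for fs = %g: need 0 < f_lo < f_hi < fs/2",
                 band[1], band[2], fs))
  band
}

# Single-pass IIR filter: MA stage by convolution, AR stage by the
# recursive filter (equivalent to a direct-form difference equation with
# zero initial conditions).
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  ma <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  ma <- ma[nb:(nb + length(x) - 1)]
  as.numeric(stats::filter(ma, -a[-1] / a[1], method = "recursive")) / a[1]
}

# Forward-backward IIR filtering with odd-reflection edge padding of length
# 3 * (max(length(a), length(b))), the standard zero-phase convention.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * max(length(a), length(b))
  if (n <= pad)
    stop(sprintf("signal too short for stable zero-phase filtering (need > %d samples, got %d)",
                 pad, n))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Fixed per-recording preprocessing
#'
#' Applies the fixed preprocessing chain to every channel of a recording:
#' energy normalization followed by frequency-domain line-noise removal.
#' The per-configuration bandpass is applied later, at encoding time, because
#' the passband is a tunable model parameter.
#'
#' @param rec an [eeg_recording()].
#' @param line_freqs line-noise frequencies to remove; frequencies at or
#'   above Nyquist for this recording are dropped with a warning only if all
#'   are invalid.
#' @return a preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, line_freqs = c(60, 180, 200)) {
  usable <- line_freqs[line_freqs < rec$fs / 2]
  dat <- apply(rec$data, 2, function(x) {
    x <- normalize_energy(x)
    if (length(usable)) x <- remove_line_noise(x, rec$fs, usable)
    x
  })
  out <- rec
  out$data <- dat
  colnames(out$data) <- rec$channels
  out
}

#' Truncate a recording to its leading fraction
#'
#' Keeps the first `ceiling(fraction * N)` samples of every channel,
#' discarding the end of the recording.
#'
#' @param rec an [eeg_recording()].
#' @param fraction retained fraction in (0, 1].
#' @return truncated `eeg_recording`.
#' @export
truncate_recording <- function(rec, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  keep <- ceiling(fraction * nrow(rec$data))
  out <- rec
  out$data <- rec$data[seq_len(keep), , drop = FALSE]
  out
}
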