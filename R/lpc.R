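#' Fit a linear predictive coding (autoregressive) model
#'
#' Encodes a time series as `K` LPC coefficients using the autocorrelation
#' method solved by the Levinson-Durbin recursion. The stored sign convention
#' writes the model as `x(n) = eps(n) - sum_i a_i x(n - i)`, i.e. the AR
#' polynomial is `A(z) = 1 + sum_i a_i z^-i`; the autocorrelation method
#' guarantees all roots of `A(z)` lie inside the unit circle.
#'
#' @param x numeric vector, length at least `10 * K`, not constant.
#' @param K model order (number of coefficients), `K >= 1`.
#' @param fs sampling rate in Hz, kept for spectral interpretation.
#' @return an object of class `lpc_model`: list with `order`, `coefficients`
#'   (`a_1..a_K`), `residual_variance` (final prediction-error power) and
#'   `fs`.
#' @export
fit_lpc <- function(x, K, fs = NA_real_) {
  K <- as.integer(K)
  if (K < 1L) stop("LPC order must be at least 1")
  n <- length(x)
  if (n < 10L * K)
    stop(sprintf("signal too short for order %d (need >= %d samples, got %d)",
                 K, 10L * K, n))
  if (stats::var(x) == 0) stop("cannot fit LPC to a constant signal")
  r <- autocorr_biased(x, K)
  fit <- levinson_durbin(r, K)
  structure(
    list(order = K, coefficients = fit$a, residual_variance = fit$err,
         fs = as.numeric(fs)),
    class = "lpc_model")
}

# biased sample autocorrelation r(0..K): r(k) = (1/N) sum x(n) x(n+k)
autocorr_biased <- function(x, K) {
  n <- length(x)
  vapply(0:K, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
}

# Levinson-Durbin recursion on autocorrelations r(0..K). Returns the
# coefficients of A(z) = 1 + a_1 z^-1 + ... + a_K z^-K and the final
# prediction-error power.
levinson_durbin <- function(r, K) {
  a <- numeric(0)
  err <- r[1]
  if (err <= 0) stop("non-positive zero-lag autocorrelation")
  for (m in seq_len(K)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc + sum(a * r[m:2])
    k <- -acc / err
    a <- if (m == 1) k else c(a + k * rev(a), k)
    err <- err * (1 - k^2)
  }
  list(a = a, err = err)
}

#' @export
print.lpc_model <- function(x, ...) {
  cat(sprintf("LPC model, order %d (fs = %g Hz)\n", x$order, x$fs))
  cat("  a:", paste(sprintf("%.4f", x$coefficients), collapse = " "), "\n")
  cat(sprintf("  residual variance: %.6g\n", x$residual_variance))
  invisible(x)
}

#' Model power spectrum implied by an LPC fit
#'
#' Evaluates `sigma^2 / |A(exp(i 2 pi f / fs))|^2` on a frequency grid: the
#' all-pole spectral density the LPC coefficients encode.
#'
#' @param model an `lpc_model` with known `fs`.
#' @param freqs frequencies in Hz, all within `[0, fs/2]`.
#' @return numeric vector of spectral density values, one per frequency.
#' @export
lpc_spectrum <- function(model, freqs) {
  fs <- model$fs
  if (!is.finite(fs)) stop("model has no sampling rate context")
  if (any(freqs < 0 | freqs > fs / 2))
    stop("frequencies must lie in [0, fs/2]")
  a <- model$coefficients
  k <- seq_along(a)
  vapply(freqs, function(f) {
    A <- 1 + sum(a * exp(-2i * pi * f * k / fs))
    model$residual_variance / Mod(A)^2
  }, 0)
}

#' Oscillatory modes of an LPC model
#'
#' Computes the roots of the AR polynomial and reports each complex-conjugate
#' pole pair (its positive-angle member) as an oscillatory mode: frequency
#' `angle * fs / (2 pi)`, pole magnitude `|root|`, and amplitude defined as
#' the model spectral density evaluated at the mode frequency. Real roots map
#' to modes at 0 Hz (positive root) or `fs/2` (negative root). Modes are
#' sorted by descending amplitude.
#'
#' @param model an `lpc_model` with known `fs`.
#' @return data.frame with columns `frequency`, `amplitude`,
#'   `pole_magnitude`, at most one row per conjugate pair.
#' @export
oscillatory_modes <- function(model) {
  a <- model$coefficients
  fs <- model$fs
  if (!is.finite(fs)) stop("model has no sampling rate context")
  # roots of z^K + a_1 z^(K-1) + ... + a_K (equivalently of A(z) off z = 0)
  roots <- polyroot(rev(c(1, a)))
  # keep real roots and the positive-angle member of each conjugate pair
  roots <- roots[Im(roots) > -1e-9]
  if (!length(roots))
    return(data.frame(frequency = numeric(0), amplitude = numeric(0),
                      pole_magnitude = numeric(0)))
  freq <- vapply(roots, function(z) {
    if (abs(Im(z)) <= 1e-9) {
      if (Re(z) >= 0) 0 else fs / 2
    } else {
      Arg(z) * fs / (2 * pi)
    }
  }, 0)
  mag <- pmin(Mod(roots), 1)
  amp <- lpc_spectrum(model, pmin(pmax(freq, 0), fs / 2))
  out <- data.frame(frequency = freq, amplitude = amp, pole_magnitude = mag)
  out <- out[order(-out$amplitude), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize / deserialize an LPC model as JSON
#' @param model an `lpc_model`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (or `path` invisibly when writing to file).
#' @export
lpc_to_json <- function(model, path = NULL) {
  obj <- list(order = model$order, coefficients = model$coefficients,
              residual_variance = model$residual_variance, fs = model$fs)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lpc_to_json
#' @param json JSON string or file path produced by [lpc_to_json()].
#' @export
lpc_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(
    list(order = as.integer(obj$order), coefficients = as.numeric(obj$coefficients),
         residual_variance = as.numeric(obj$residual_variance),
         fs = as.numeric(obj$fs)),
    class = "lpc_model")
}
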