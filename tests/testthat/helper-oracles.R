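# Independent oracles and small fixture builders used across the suite.

# Simulate from a stable AR model given coefficients in the convention
# x(n) = eps(n) - sum a_i x(n-i); burn-in discarded.
simulate_ar <- function(a, n, burn = 500) {
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, -a, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

# Random stable AR coefficients via reflection coefficients (each in
# (-1, 1) guarantees stability), converted by the step-up recursion.
random_stable_ar <- function(K, kmax = 0.8) {
  refl <- stats::runif(K, -kmax, kmax)
  a <- numeric(0)
  for (k in refl) a <- if (!length(a)) k else c(a + k * rev(a), k)
  a
}

# Direct Yule-Walker solve from biased sample autocorrelations: an
# independent linear-system oracle for the Levinson-Durbin path.
yule_walker_direct <- function(x, K) {
  n <- length(x)
  r <- vapply(0:K, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
  R <- stats::toeplitz(r[1:K])
  as.numeric(solve(R, r[2:(K + 1)]))   # phi; a = -phi in our convention
}

# Brute-force point-to-affine-subspace distance: minimize over basis
# coordinates by unconstrained least squares.
lsq_distance <- function(a, bias, basis) {
  fit <- stats::lsfit(basis, a - bias, intercept = FALSE)
  sqrt(sum(fit$residuals^2))
}

# AUC by explicit ROC trapezoid integration (impaired = low-index class).
trapezoid_auc <- function(indices, impaired) {
  th <- sort(unique(c(-Inf, indices, Inf)))
  sens <- vapply(th, function(t) mean(indices[impaired] < t), 0)
  fpr <- vapply(th, function(t) mean(indices[!impaired] < t), 0)
  ord <- order(fpr, sens)
  sum(diff(fpr[ord]) * (utils::head(sens[ord], -1) + utils::tail(sens[ord], -1)) / 2)
}

# Tiny handmade cohort: per-subject single resonator whose frequency rises
# linearly with the score on informative electrodes, plus white noise.
# Cheap enough for unit tests (fs 100 Hz, short recordings).
toy_cohort <- function(scores, fs = 100, duration = 10,
                       electrodes = c("E1", "E2"), informative = "E1",
                       f_lo = 6, f_hi = 11, noise_sd = 0.4, seed = 1) {
  set.seed(seed)
  n <- length(scores)
  ids <- sprintf("T%02d", seq_len(n))
  nsamp <- round(fs * duration)
  sc01 <- (scores - min(scores)) / max(diff(range(scores)), 1)
  recs <- lapply(seq_len(n), function(i) {
    dat <- sapply(electrodes, function(el) {
      if (el %in% informative) {
        f <- f_lo + sc01[i] * (f_hi - f_lo)
        th <- 2 * pi * f / fs
        y <- as.numeric(stats::filter(stats::rnorm(nsamp),
                                      c(2 * 0.95 * cos(th), -0.95^2),
                                      method = "recursive"))
        y / stats::sd(y) + noise_sd * stats::rnorm(nsamp)
      } else {
        stats::rnorm(nsamp)
      }
    })
    eeg_recording(dat, fs, electrodes, ids[i])
  })
  names(recs) <- ids
  table <- data.frame(id = ids, age = round(stats::rnorm(n, 68, 8), 1),
                      sex = rep(c("M", "F"), length.out = n), group = "PD",
                      moca = scores, stringsAsFactors = FALSE)
  list(recordings = recs, table = table)
}
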