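# Shared fixtures, built in code at test time.

make_tone <- function(freq, dur = 0.5, fs = 44100, amp = 0.5,
                      label = sprintf("tone%g", freq)) {
  waveform(amp * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs)),
           fs, label)
}

white_noise_wave <- function(dur = 0.5, fs = 44100, seed = 1,
                             label = "noise") {
  waveform(withr::with_seed(seed, rnorm(round(dur * fs), sd = 0.1)),
           fs, label)
}

# Minimal cochleagram wrapper around an explicit energy matrix, for testing
# the marginal summaries without running the filterbank.
toy_cochleagram <- function(energy) {
  structure(
    list(energy = energy,
         center_freqs = erb_center_frequencies(nrow(energy), 50, 20000),
         frame_len = 0.020, frame_hop = 0.010, fs_origin = 44100),
    class = "cochleagram"
  )
}

# Location of the dominant spectral peak by discrete Fourier analysis
# (independent of the package's filterbank).
fft_peak_hz <- function(w) {
  n <- length(w$samples)
  spec <- Mod(stats::fft(w$samples))[seq_len(floor(n / 2))]
  (which.max(spec) - 1) * w$fs / n
}

# Long-run average spectrum via segment-averaged periodograms, for noisy
# signals where a single DFT is too ragged.
welch_peak_hz <- function(w, seg = 8192) {
  x <- w$samples
  n_seg <- floor(length(x) / seg)
  acc <- numeric(seg %/% 2)
  for (i in seq_len(n_seg)) {
    chunk <- x[((i - 1) * seg + 1):(i * seg)]
    acc <- acc + Mod(stats::fft(chunk))[seq_len(seg %/% 2)]^2
  }
  (which.max(acc) - 1) * w$fs / seg
}

# Iteratively reweighted least squares for logistic regression: the
# independent oracle against which glm-based fits are compared.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- mu * (1 - mu)
    wts <- pmax(wts, 1e-12)
    z <- eta + (y - mu) / wts
    beta_new <- solve(crossprod(X, wts * X), crossprod(X, wts * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.vector(beta)
}
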