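# Rolling-sound family: noise carriers with shape-dependent spectra and
# smooth vs. sharp amplitude envelopes, plus the envelope-transplantation
# machinery (extract an envelope, impose it on a spectrum-matched noise
# carrier) used to dissociate spectral from temporal cues.

#' Construct an amplitude envelope
#'
#' @param values Nonnegative amplitude sequence at the envelope rate.
#' @param rate Envelope sampling rate in Hz.
#' @return An object of class `"envelope"`.
#' @export
envelope <- function(values, rate) {
  values <- as.numeric(values)
  if (length(values) < 1 || !all(is.finite(values)) || any(values < 0)) {
    abort("Envelope values must be finite and nonnegative.",
          class = "roundsound_argument_error")
  }
  check_number(rate, "rate", lower = .Machine$double.eps)
  structure(list(values = values, rate = rate), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d points @ %g Hz (%.3f s)\n", length(x$values),
              x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' Extract the amplitude envelope of a waveform
#'
#' Full-wave rectification followed by low-pass smoothing with a Hann kernel
#' of width `1 / cutoff` seconds, then decimation to the envelope rate by
#' linear interpolation. The operation is linear in the input gain:
#' `extract_envelope(a * w) == a * extract_envelope(w)`.
#'
#' @param w A [waveform()].
#' @param cutoff Smoothing cutoff in Hz (kernel width `1 / cutoff` s).
#'   Default 32, which preserves fluctuations at the 40 ms scale.
#' @param env_rate Output envelope rate in Hz. Default 1000.
#' @return An [envelope()].
#' @export
extract_envelope <- function(w, cutoff = 32, env_rate = 1000) {
  stopifnot(is_waveform(w))
  check_number(cutoff, "cutoff", lower = .Machine$double.eps)
  kernel <- hann_window(max(3, round(w$fs / cutoff)))
  kernel <- kernel / sum(kernel)
  rect <- abs(w$samples)
  full <- stats::convolve(rect, rev(kernel), type = "open")
  offset <- (length(kernel) - 1) %/% 2
  full <- full[seq_len(length(rect)) + offset]
  t_in <- (seq_along(rect) - 1) / w$fs
  t_out <- seq(0, max(t_in), by = 1 / env_rate)
  vals <- approx(t_in, full, xout = t_out, rule = 2)$y
  envelope(pmax(vals, 0), env_rate)
}

#' Maximal dB swing of an envelope within a sliding window
#'
#' Scans the interior of an envelope (first and last `trim` fraction excluded,
#' so onset/offset ramps are ignored) with a sliding window and returns the
#' largest max/min range expressed in dB. `window = Inf` uses the whole
#' interior, which bounds the swing of every larger window.
#'
#' @param env An [envelope()].
#' @param window Window length in seconds, or `Inf`.
#' @param trim Edge fraction excluded at each end. Default 0.1.
#' @return Largest swing in dB across window placements.
#' @export
envelope_swing_db <- function(env, window = Inf, trim = 0.1) {
  stopifnot(inherits(env, "envelope"))
  v <- env$values
  n <- length(v)
  n_edge <- floor(trim * n)
  v <- v[seq(n_edge + 1, n - n_edge)]
  v <- pmax(v, 1e-12) # dB guard
  if (!is.finite(window)) {
    return(amp_to_db(max(v) / min(v)))
  }
  wlen <- max(2, round(window * env$rate))
  if (wlen >= length(v)) {
    return(amp_to_db(max(v) / min(v)))
  }
  swings <- vapply(seq_len(length(v) - wlen + 1), function(i) {
    seg <- v[i:(i + wlen - 1)]
    max(seg) / min(seg)
  }, numeric(1))
  amp_to_db(max(swings))
}

#' Stationary noise shaped to a target mean spectrum
#'
#' Generates noise whose long-run cochleagram mean spectrum matches the target
#' per-channel profile: a seeded white-noise draw is shaped in the frequency
#' domain, analyzed, and the per-channel gains corrected iteratively until all
#' channels holding at least 1 % of the total target energy agree within 3 dB
#' (or a maximum of 12 rounds).
#'
#' @param profile Target per-channel mean energies (length = channel count,
#'   nonzero).
#' @param duration Output duration in seconds.
#' @param seed Integer seed; same seed, same waveform.
#' @param fs Sampling rate. Default 44,100 Hz.
#' @param n_channels,fmin,fmax Filterbank geometry the profile refers to.
#' @param tol_db Per-channel tolerance in dB. Default 3.
#' @param label Stimulus label.
#' @return A [waveform()].
#' @export
shaped_noise <- function(profile, duration, seed = 1, fs = 44100,
                         n_channels = length(profile), fmin = 50,
                         fmax = 20000, tol_db = 3, label = "shaped_noise") {
  profile <- as.numeric(profile)
  if (all(profile == 0)) {
    abort("Cannot shape noise to an all-zero spectral profile.",
          class = "roundsound_degenerate_input_error")
  }
  if (any(profile < 0)) {
    abort("`profile` must be nonnegative.", class = "roundsound_argument_error")
  }
  cfs <- erb_center_frequencies(n_channels, fmin, fmax)
  n <- round(duration * fs)
  x0 <- withr::with_seed(seed, rnorm(n))
  X0 <- fft(x0)
  freqs <- (0:(n - 1)) * fs / n
  fold <- pmin(freqs, fs - freqs) # two-sided spectrum frequencies

  qualifying <- profile >= 0.01 * sum(profile)
  gains <- rep(1, n_channels)
  wave <- NULL
  for (iter in seq_len(12)) {
    # Interpolate per-channel amplitude gains over the DFT grid (log-f axis,
    # edge-held beyond the channel range).
    amp <- approx(cfs, sqrt(pmax(gains * profile, 0)), xout = fold,
                  rule = 2)$y
    x <- Re(fft(X0 * amp, inverse = TRUE)) / n
    wave <- waveform(x, fs, label)
    measured <- unname(mean_spectrum(cochleagram(wave, n_channels = n_channels,
                                                 fmin = fmin, fmax = fmax)))
    err <- 10 * log10(pmax(measured, 1e-300) / pmax(profile, 1e-300))
    if (max(abs(err[qualifying])) <= tol_db * 0.8) break
    # Global level first (the raw noise PSD is arbitrary), then a clamped
    # per-channel correction on top of it.
    ratio <- profile / pmax(measured, 1e-300)
    g_glob <- sum(profile[qualifying]) / sum(measured[qualifying])
    gains <- gains * g_glob * ifelse(qualifying, clamp(ratio / g_glob, 0.25, 4), 1)
  }
  wave
}

#' Impose an envelope on a noise carrier
#'
#' Upsamples the envelope to the carrier rate, multiplies it into the leading
#' portion of the carrier, and RMS-normalizes the result. The output duration
#' equals the envelope duration.
#'
#' @param env An [envelope()].
#' @param carrier A [waveform()] at least as long as the envelope.
#' @param target_rms Output RMS. Default 0.05.
#' @param label Output label; defaults to the carrier label with a
#'   `"_xplant"` suffix.
#' @return A [waveform()].
#' @export
transplant_envelope <- function(env, carrier, target_rms = 0.05,
                                label = paste0(carrier$label, "_xplant")) {
  stopifnot(inherits(env, "envelope"), is_waveform(carrier))
  n_out <- round(length(env$values) / env$rate * carrier$fs)
  if (n_out > length(carrier$samples)) {
    abort("Carrier is shorter than the envelope.",
          class = "roundsound_argument_error")
  }
  t_env <- (seq_along(env$values) - 1) / env$rate
  t_out <- (seq_len(n_out) - 1) / carrier$fs
  env_up <- approx(t_env, env$values, xout = t_out, rule = 2)$y
  out <- carrier$samples[seq_len(n_out)] * env_up
  normalize_rms(waveform(out, carrier$fs, label), target_rms)
}

# Carrier noise for a rolling sound: broadband noise with a first-order
# spectral emphasis (smooth shapes rumble low, sharp shapes hiss high) plus a
# gentle surface tilt (wood darker than plastic).
rolling_carrier <- function(n, shape, surface, fs) {
  x <- rnorm(n)
  if (shape == "smooth") {
    # one-pole low-pass emphasis around 800 Hz
    a <- exp(-2 * pi * 800 / fs)
    x <- as.numeric(signal::filter(1 - a, c(1, -a), x))
  } else {
    # first-order high-pass emphasis around 1500 Hz
    a <- exp(-2 * pi * 1500 / fs)
    x <- as.numeric(signal::filter(c(1, -1), c(1, -a), x))
  }
  if (surface == "wood") {
    a <- 0.25 # mild extra low tilt
    x <- as.numeric(signal::filter(1 - a, c(1, -a), x))
  } else {
    x <- as.numeric(signal::filter(c(1, -0.25), 1, x)) # mild pre-emphasis
  }
  x
}

#' Synthesize a rolling sound
#'
#' About 200 ms of shaped noise whose amplitude envelope encodes the rolling
#' object's contour: a `"smooth"` trajectory modulates gently (a few-Hz
#' sinusoid, total swing about 2 dB, staying below 6 dB over any window longer
#' than 40 ms), while a `"sharp"` trajectory contains brief notches dropping
#' by well over 8 dB within less than 40 ms. Smooth rolls use a low-frequency
#' carrier emphasis, sharp rolls a high-frequency one; the surface preset adds
#' a mild spectral tilt (wood darker, plastic brighter).
#'
#' @param shape `"smooth"` or `"sharp"`.
#' @param surface `"wood"` or `"plastic"`.
#' @param duration Duration in seconds. Default 0.2.
#' @param fs Sampling rate. Default 44,100 Hz.
#' @param seed Integer seed.
#' @param label Stimulus label.
#' @param target_rms Output RMS. Default 0.05.
#' @return A [waveform()].
#' @export
make_rolling <- function(shape = c("smooth", "sharp"),
                         surface = c("wood", "plastic"), duration = 0.2,
                         fs = 44100, seed = 1,
                         label = sprintf("roll_%s_%s", shape[1], surface[1]),
                         target_rms = 0.05) {
  shape <- match.arg(shape)
  surface <- match.arg(surface)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  withr::with_seed(seed, {
    x <- rolling_carrier(n, shape, surface, fs)
    if (shape == "smooth") {
      f_mod <- stats::runif(1, 3, 6)
      phi <- stats::runif(1, 0, 2 * pi)
      env <- 1 + 0.12 * sin(2 * pi * f_mod * t + phi)
    } else {
      env <- rep(1, n)
      centers <- c(0.2, 0.5, 0.8) * duration +
        stats::runif(3, -0.05, 0.05) * duration
      for (ctr in centers) {
        # 5 ms fall, 10 ms floor at 0.15 (-16.5 dB), 5 ms rise
        seg <- abs(t - ctr)
        env[seg < 0.005] <- pmin(env[seg < 0.005], 0.15)
        ramp <- seg >= 0.005 & seg < 0.010
        env[ramp] <- pmin(env[ramp],
                          0.15 + 0.85 * (seg[ramp] - 0.005) / 0.005)
      }
    }
  })
  x <- apply_ramps(x * env, round(0.005 * fs))
  normalize_rms(waveform(x, fs, label), target_rms)
}

#' Rolling-sounds corpus with envelope transplantation
#'
#' Builds the 36-stimulus design: 12 "original" rolls (2 contour shapes x 2
#' surfaces x 3 seeded instances), then extracts the amplitude envelope of
#' each original and imposes it on two spectrum-matched noise carriers -- a
#' low-frequency carrier shaped to the mean spectrum of the smooth originals
#' and a high-frequency carrier shaped to the mean spectrum of the sharp
#' originals -- yielding 24 additional synthetic stimuli that cross Acoustic
#' Envelope (smooth/sharp) with Spectral Balance (LF/HF), six per cell.
#'
#' @param master_seed Integer seed; reproduces the corpus bitwise.
#' @return A tibble: `stimulus`, `type` (`"original"`/`"synthetic"`),
#'   `envelope_shape`, `surface` (`NA` for synthetic), `carrier` (`NA` for
#'   originals, else `"LF"`/`"HF"`), `instance`, `seed`, `wave` list-column.
#' @export
rolling_corpus <- function(master_seed = 1) {
  design <- tidyr::expand_grid(shape = c("smooth", "sharp"),
                               surface = c("wood", "plastic"),
                               instance = 1:3)
  seeds <- derive_seeds(master_seed, nrow(design) + 2)
  design$seed <- seeds[seq_len(nrow(design))]
  design <- dplyr::mutate(
    design,
    stimulus = sprintf("roll_%s_%s_i%d", .data$shape, .data$surface,
                       .data$instance),
    wave = purrr::pmap(list(.data$shape, .data$surface, .data$seed,
                            .data$stimulus),
                       function(sh, su, sd, lab) {
                         make_rolling(sh, su, seed = sd, label = lab)
                       })
  )

  originals <- tibble::tibble(
    stimulus = design$stimulus,
    type = "original",
    envelope_shape = design$shape,
    surface = design$surface,
    carrier = NA_character_,
    instance = design$instance,
    seed = design$seed,
    wave = design$wave
  )

  # Mean spectral profile of each shape class -> two shaped-noise carriers.
  profile_of <- function(shape) {
    waves <- originals$wave[originals$envelope_shape == shape]
    profs <- vapply(waves,
                    function(w) unname(mean_spectrum(cochleagram(w))),
                    numeric(64))
    rowMeans(profs)
  }
  carrier_dur <- 0.25 # leaves headroom over the 0.2 s envelopes
  carriers <- list(
    LF = shaped_noise(profile_of("smooth"), carrier_dur,
                      seed = seeds[nrow(design) + 1], label = "carrier_LF"),
    HF = shaped_noise(profile_of("sharp"), carrier_dur,
                      seed = seeds[nrow(design) + 2], label = "carrier_HF")
  )

  synth <- tidyr::expand_grid(src = seq_len(nrow(originals)),
                              carrier = c("LF", "HF"))
  synth_rows <- purrr::pmap(list(synth$src, synth$carrier), function(i, cr) {
    env <- extract_envelope(originals$wave[[i]])
    lab <- sprintf("%s_on_%s", originals$stimulus[i], cr)
    tibble::tibble(
      stimulus = lab,
      type = "synthetic",
      envelope_shape = originals$envelope_shape[i],
      surface = NA_character_,
      carrier = cr,
      instance = originals$instance[i],
      seed = originals$seed[i],
      wave = list(transplant_envelope(env, carriers[[cr]], label = lab))
    )
  })
  dplyr::bind_rows(originals, purrr::list_rbind(synth_rows))
}
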