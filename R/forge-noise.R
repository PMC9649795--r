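# Noise-band stimulus family: white noise through a second-order resonator
# (bandwidth = fc/10), amplitude-modulated by an interior dip. The factorial
# corpus crosses 8 center frequencies with 4 dip amplitudes (32 stimuli).

# Two-pole resonator with approximately the requested -3 dB bandwidth,
# normalized to unit gain at the center frequency.
resonator_filter <- function(x, fc, bw, fs) {
  theta <- 2 * pi * fc / fs
  r <- exp(-pi * bw / fs)
  a <- c(1, -2 * r * cos(theta), r^2)
  y <- signal::filter(1, a, x)
  z1 <- exp(-1i * theta)
  g <- abs(1 / (1 + a[2] * z1 + a[3] * z1^2))
  as.numeric(y) / g
}

#' Synthesize a dipped noise-band stimulus
#'
#' A 500 ms band of white noise centered at `fc` with bandwidth `fc / 10`,
#' whose amplitude envelope is 1 everywhere except a dip window (225-275 ms)
#' where it equals `dip_amp`: 1 means no dip (full temporal continuity), 0 a
#' completely silent interval. Short raised-cosine ramps (5 ms at the ends,
#' 2 ms inside the dip window) avoid spectral splatter from discontinuities.
#'
#' @param fc Center frequency in Hz.
#' @param dip_amp Relative dip amplitude in `[0, 1]`.
#' @param duration Stimulus duration in seconds. Default 0.5.
#' @param dip_window Two-element vector: dip start and end in seconds.
#'   Default `c(0.225, 0.275)`.
#' @param fs Sampling rate. Default 44,100 Hz.
#' @param seed Integer seed; the same seed gives a bitwise-identical waveform.
#' @param label Stimulus label. Default encodes `fc` and `dip_amp`.
#' @return A [waveform()], peak-normalized to 0.9.
#' @export
make_noise_band <- function(fc, dip_amp, duration = 0.5,
                            dip_window = c(0.225, 0.275), fs = 44100,
                            seed = 1,
                            label = sprintf("nb_fc%04d_dip%03d", round(fc),
                                            round(100 * dip_amp))) {
  check_number(fc, "fc", lower = 1)
  check_number(dip_amp, "dip_amp", lower = 0, upper = 1)
  check_number(duration, "duration", lower = 0.01)
  if (dip_window[1] <= 0 || dip_window[2] >= duration ||
      dip_window[2] <= dip_window[1]) {
    abort("`dip_window` must lie strictly inside (0, duration).",
          class = "roundsound_argument_error")
  }
  n <- round(duration * fs)
  x <- withr::with_seed(seed, rnorm(n))
  x <- resonator_filter(x, fc, fc / 10, fs)
  x <- apply_ramps(x, round(0.005 * fs))

  env <- rep(1, n)
  i0 <- round(dip_window[1] * fs) + 1
  i1 <- round(dip_window[2] * fs)
  env[i0:i1] <- dip_amp
  # 2 ms ramps just inside the dip window; the flanks stay at constant 1.
  nr <- round(0.002 * fs)
  env[i0:(i0 + nr - 1)] <- 0.5 * (1 + dip_amp) +
    0.5 * (1 - dip_amp) * cos(pi * seq(0, 1, length.out = nr))
  env[(i1 - nr + 1):i1] <- rev(env[i0:(i0 + nr - 1)])
  x <- x * env

  waveform(0.9 * x / max(abs(x)), fs, label)
}

#' Full factorial noise-band corpus
#'
#' The 32-stimulus design: 8 center frequencies (300-1200 Hz) crossed with 4
#' dip amplitudes (0, 0.1, 0.5, 1), one seeded noise realization each.
#'
#' @param master_seed Integer seed from which per-stimulus seeds are derived;
#'   the same master seed reproduces the corpus bitwise.
#' @param fc_values Center frequencies. Default
#'   `c(300, 500, 600, 700, 800, 900, 1000, 1200)`.
#' @param dip_values Dip amplitudes. Default `c(0, 0.1, 0.5, 1)`.
#' @return A tibble with columns `stimulus`, `fc`, `dip_amp`, `seed`, and a
#'   `wave` list-column of [waveform()] objects.
#' @export
noise_band_corpus <- function(master_seed = 1,
                              fc_values = c(300, 500, 600, 700, 800, 900,
                                            1000, 1200),
                              dip_values = c(0, 0.1, 0.5, 1)) {
  design <- tidyr::expand_grid(fc = fc_values, dip_amp = dip_values)
  design$seed <- derive_seeds(master_seed, nrow(design))
  design <- dplyr::mutate(
    design,
    stimulus = sprintf("nb_fc%04d_dip%03d", round(.data$fc),
                       round(100 * .data$dip_amp)),
    wave = purrr::pmap(list(.data$fc, .data$dip_amp, .data$seed,
                            .data$stimulus),
                       function(fc, dip, sd, lab) {
                         make_noise_band(fc, dip, seed = sd, label = lab)
                       })
  )
  dplyr::select(design, "stimulus", "fc", "dip_amp", "seed", "wave")
}
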