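#' Construct a waveform
#'
#' A waveform is the universal input of the analysis pipeline: a finite mono
#' amplitude sequence (nominal range \[-1, 1\]) with its sampling rate and a
#' free-text stimulus label.
#'
#' @param samples Numeric vector of amplitudes; all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Stimulus identifier carried through analysis tables.
#' @return An object of class `"waveform"`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 44100)), 44100, "a4")
#' w
#' @export
waveform <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1) {
    abort("A waveform needs at least one sample.", class = "roundsound_argument_error")
  }
  if (!all(is.finite(samples))) {
    abort("Waveform samples must all be finite.", class = "roundsound_argument_error")
  }
  check_number(fs, "fs", lower = .Machine$double.eps)
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1]),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d samples @ %g Hz (%.3f s), rms %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, wave_duration(x), wave_rms(x)))
  invisible(x)
}

#' @rdname waveform
#' @param x Object to test.
#' @export
is_waveform <- function(x) inherits(x, "waveform")

#' Waveform duration in seconds
#' @param w A [waveform()].
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
wave_duration <- function(w) length(w$samples) / w$fs

#' Root-mean-square amplitude of a waveform
#' @param w A [waveform()].
#' @return The RMS amplitude (dimensionless).
#' @export
wave_rms <- function(w) sqrt(mean(w$samples^2))

#' Normalize a waveform to a target RMS amplitude
#'
#' Rescales the samples so that the output RMS equals `target_rms`. This is the
#' intensity normalization applied to every stimulus before analysis: the
#' Balance index is gain-dependent (it scales with squared amplitude), so all
#' stimuli are brought to a common level first. The operation is idempotent and
#' removes any prior gain.
#'
#' @param w A [waveform()].
#' @param target_rms Target RMS amplitude (> 0). Default 0.05.
#' @return A [waveform()] with `wave_rms(out) == target_rms`.
#' @export
normalize_rms <- function(w, target_rms = 0.05) {
  stopifnot(is_waveform(w))
  check_number(target_rms, "target_rms", lower = .Machine$double.eps)
  r <- wave_rms(w)
  if (r == 0) {
    abort("Cannot RMS-normalize an all-zero waveform.",
          class = "roundsound_degenerate_input_error")
  }
  waveform(w$samples * (target_rms / r), w$fs, w$label)
}

#' Resample a waveform to a new rate
#'
#' Polyphase rational-ratio resampling (via the signal package). Duration is
#' preserved within one sample period. The canonical internal rate is 44,100 Hz:
#' the filterbank's top channel sits at 20 kHz, so analysis requires
#' `fs >= 40,000` Hz and loaders resample on ingest.
#'
#' @param w A [waveform()].
#' @param fs_target Target sampling rate in Hz (> 0).
#' @return A [waveform()] at `fs_target`.
#' @export
resample_wave <- function(w, fs_target) {
  stopifnot(is_waveform(w))
  check_number(fs_target, "fs_target", lower = .Machine$double.eps)
  if (fs_target == w$fs) {
    return(w)
  }
  # Rational ratio p/q from the two rates; rates are integral in practice.
  scale <- 1
  fa <- w$fs
  fb <- fs_target
  while (abs(fa - round(fa)) > 1e-9 || abs(fb - round(fb)) > 1e-9) {
    fa <- fa * 10
    fb <- fb * 10
    scale <- scale * 10
    if (scale > 1e6) {
      abort("Cannot express the resampling ratio as a small rational.",
            class = "roundsound_argument_error")
    }
  }
  g <- gcd(round(fa), round(fb))
  p <- round(fb) / g
  q <- round(fa) / g
  y <- signal::resample(w$samples, p, q)
  n_out <- round(length(w$samples) * fs_target / w$fs)
  if (length(y) >= n_out) {
    y <- y[seq_len(n_out)]
  } else {
    y <- c(y, rep(0, n_out - length(y)))
  }
  waveform(y, fs_target, w$label)
}
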