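#' Gammatone cochleagram of a waveform
#'
#' Passes the waveform through the 64-channel gammatone filterbank and returns
#' per-channel frame energies: the squared filter outputs averaged in
#' rectangular frames (20 ms length, 10 ms hop by default). Energies are kept
#' on a linear power scale throughout because the Balance index sums them and
#' the Continuity index takes a ratio; no dB compression is applied.
#'
#' @param w A [waveform()]. Its sampling rate must be at least `2 * fmax`;
#'   resample first if not (see [resample_wave()]).
#' @param n_channels Number of filterbank channels. Default 64.
#' @param fmin,fmax Center frequencies of the first and last channel, in Hz.
#'   Defaults 50 and 20,000.
#' @param frame_len,frame_hop Frame length and hop in seconds. Defaults 0.020
#'   and 0.010.
#' @return An object of class `"cochleagram"`: a list with `energy`
#'   (channels x frames matrix of nonnegative linear-power energies),
#'   `center_freqs`, `frame_len`, `frame_hop`, and `fs_origin`.
#' @examples
#' w <- waveform(sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / 44100)), 44100)
#' cg <- cochleagram(w)
#' dim(cg$energy)
#' @export
cochleagram <- function(w, n_channels = 64, fmin = 50, fmax = 20000,
                        frame_len = 0.020, frame_hop = 0.010) {
  stopifnot(is_waveform(w))
  if (w$fs < 2 * fmax) {
    abort(sprintf(
      "Sampling rate %g Hz is below the Nyquist rate for fmax = %g Hz; resample the waveform (resample_wave) to at least %g Hz first.",
      w$fs, fmax, 2 * fmax), class = "roundsound_precondition_error")
  }
  if (wave_duration(w) < frame_len) {
    abort("Waveform shorter than one analysis frame.",
          class = "roundsound_precondition_error")
  }
  cfs <- erb_center_frequencies(n_channels, fmin, fmax)
  x <- w$samples
  n <- length(x)
  fs <- w$fs

  # Zero-pad past the slowest channel's ring-out so DFT-grid filtering matches
  # the IIR recursion (lowest channel decays to ~1e-4 within 0.1 s).
  nfft <- nextn(n + ceiling(0.1 * fs), 2)
  X <- fft(c(x, numeric(nfft - n)))
  # Real input: evaluate responses on the half spectrum and mirror conjugates.
  half <- nfft %/% 2
  z1h <- exp(-2i * pi * (0:half) / nfft)
  z2h <- z1h * z1h
  Xh <- X[seq_len(half + 1)]

  flen <- round(frame_len * fs)
  fhop <- round(frame_hop * fs)
  n_frames <- max(1L, floor((n - flen) / fhop) + 1L)
  starts <- (seq_len(n_frames) - 1L) * fhop

  energy <- matrix(0, nrow = n_channels, ncol = n_frames)
  for (i in seq_len(n_channels)) {
    Yh <- Xh * gammatone_response_z(cfs[i], fs, z1h, z2h)
    Y <- c(Yh, Conj(Yh[seq(half, 2)]))
    y <- Re(fft(Y, inverse = TRUE))[seq_len(n)] / nfft
    cs <- c(0, cumsum(y^2))
    energy[i, ] <- (cs[starts + flen + 1L] - cs[starts + 1L]) / flen
  }
  energy[energy < 0] <- 0 # guard against negative rounding noise

  structure(
    list(energy = energy, center_freqs = cfs, frame_len = frame_len,
         frame_hop = frame_hop, fs_origin = fs),
    class = "cochleagram"
  )
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram> %d channels (%.0f-%.0f Hz) x %d frames (%.0f ms / %.0f ms hop)\n",
              nrow(x$energy), x$center_freqs[1],
              x$center_freqs[length(x$center_freqs)], ncol(x$energy),
              x$frame_len * 1000, x$frame_hop * 1000))
  invisible(x)
}

#' Mean spectrum of a cochleagram
#'
#' Averages spectral frames over time for each channel, yielding the spectral
#' profile `S[1..n]` that feeds the Balance index.
#'
#' @param cg A [cochleagram()].
#' @return Numeric vector of per-channel mean energies, named by center
#'   frequency (Hz).
#' @export
mean_spectrum <- function(cg) {
  stopifnot(inherits(cg, "cochleagram"))
  setNames(rowMeans(cg$energy), format(round(cg$center_freqs, 1)))
}

#' Per-frame summed energy of a cochleagram
#'
#' Sums energy across all channels for each temporal frame, yielding the
#' energy track `E[1..T]` that feeds the Continuity index.
#'
#' @param cg A [cochleagram()].
#' @return Numeric vector of length `T` (number of frames).
#' @export
frame_energies <- function(cg) {
  stopifnot(inherits(cg, "cochleagram"))
  colSums(cg$energy)
}

#' Export a cochleagram as a CSV matrix
#'
#' Writes the frames x channels energy matrix with a header row of channel
#' center frequencies (Hz); one row per frame.
#'
#' @param cg A [cochleagram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cochleagram_csv <- function(cg, path) {
  stopifnot(inherits(cg, "cochleagram"))
  m <- t(cg$energy)
  colnames(m) <- format(cg$center_freqs, trim = TRUE)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Tidy a cochleagram into a long tibble
#'
#' @param x A [cochleagram()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `center_freq`, `time`, `energy`.
#' @export
tidy.cochleagram <- function(x, ...) {
  n_ch <- nrow(x$energy)
  n_fr <- ncol(x$energy)
  tibble::tibble(
    channel = rep(seq_len(n_ch), times = n_fr),
    center_freq = rep(x$center_freqs, times = n_fr),
    time = rep((seq_len(n_fr) - 1) * x$frame_hop + x$frame_len / 2,
               each = n_ch),
    energy = as.vector(x$energy)
  )
}

#' Plot a cochleagram
#'
#' Time-frequency raster on a dB color scale (floored at -80 dB relative to
#' the maximum frame energy).
#'
#' @param object A [cochleagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cochleagram <- function(object, ...) {
  df <- tidy(object)
  ref <- max(df$energy)
  if (ref <= 0) ref <- 1
  df$db <- 10 * log10(pmax(df$energy / ref, 1e-8))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$channel,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB re max") +
    ggplot2::labs(x = "Time (s)", y = "Channel (ERB-spaced)") +
    ggplot2::theme_minimal()
}
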