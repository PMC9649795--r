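#' Spectral Balance index
#'
#' Balance at boundary channel `b` is the summed mean-spectrum energy in
#' channels 1..b minus the summed energy in channels b+1..n:
#' `sum(S[1:b]) - sum(S[(b+1):n])`. Positive values mean the stimulus carries
#' more energy below the boundary than above it ("round-sounding"); the index
#' is exactly non-decreasing in `b`, with increment `2 * S[b + 1]`.
#'
#' @param S Spectral profile: nonnegative per-channel mean energies (see
#'   [mean_spectrum()]).
#' @param b Boundary channel index, `1 <= b < length(S)`.
#' @return Balance in linear energy units.
#' @export
spectral_balance <- function(S, b) {
  if (!is.numeric(S) || length(S) < 2 || any(S < 0)) {
    abort("`S` must be a nonnegative energy profile of length >= 2.",
          class = "roundsound_argument_error")
  }
  if (!is.numeric(b) || length(b) != 1 || b != round(b) || b < 1 ||
      b >= length(S)) {
    abort(sprintf("`b` must be an integer in [1, %d].", length(S) - 1),
          class = "roundsound_argument_error")
  }
  sum(S[seq_len(b)]) - sum(S[seq(b + 1, length(S))])
}

#' Temporal Continuity index
#'
#' The log ratio of the minimum to the maximum summed frame energy inside a
#' stimulus: `log(min(E) / max(E))` (natural log). A flat envelope scores 0; a
#' deep amplitude dip scores strongly negative. The value is clamped below at
#' `floor` so that a truly silent interval (ratio 0, log -Inf) remains usable
#' in regression.
#'
#' When `edge_frac > 0`, the first and last `floor(edge_frac * T)` frames are
#' excluded from the minimum search, so onset/offset ramps are not mistaken for
#' interior dips; the maximum is taken over all frames.
#'
#' @param E Energy track: nonnegative per-frame summed energies (see
#'   [frame_energies()]).
#' @param floor Lower clamp for the log ratio. Default `log(1e-6)` (about
#'   -13.8).
#' @param edge_frac Fraction of frames at each edge excluded from the minimum
#'   search. Default 0 (use all frames).
#' @return Continuity value in `[floor, 0]`.
#' @export
temporal_continuity <- function(E, floor = log(1e-6), edge_frac = 0) {
  if (!is.numeric(E) || length(E) < 1 || any(E < 0)) {
    abort("`E` must be a nonnegative energy track.",
          class = "roundsound_argument_error")
  }
  check_number(floor, "floor", upper = 0)
  if (max(E) == 0) {
    abort("Continuity is undefined for an all-silent stimulus (max energy 0).",
          class = "roundsound_degenerate_input_error")
  }
  n <- length(E)
  n_edge <- base::floor(edge_frac * n) # `floor` is shadowed by the clamp arg
  interior <- if (n - 2 * n_edge >= 1) {
    E[seq(n_edge + 1, n - n_edge)]
  } else {
    E
  }
  val <- log(min(interior) / max(E))
  max(floor, val)
}

#' Balance and Continuity for one stimulus
#'
#' Runs the full front end on a waveform: intensity normalization, gammatone
#' cochleagram, then Balance at every candidate boundary in `b_range` from the
#' mean spectrum, and (when the stimulus is eligible) Continuity from the
#' frame-energy track with edge frames excluded from the minimum search.
#'
#' Intensity normalization happens in the model's own representation: after an
#' RMS pre-scaling, the mean spectrum is rescaled so its total energy equals
#' `target_rms^2` for every stimulus. Balance is an energy difference, so
#' cross-stimulus comparisons are only meaningful at equated level; equating
#' level in the cochlear domain (rather than raw waveform RMS) removes the
#' residual frequency dependence of the filterbank's summed power response,
#' which would otherwise leak spectrum-independent level differences into the
#' index. Continuity, a ratio, is unaffected by either scaling.
#'
#' Continuity eligibility is caller-controlled metadata: the index is only
#' meaningful for stimuli whose envelope can contain an interior dip (e.g.
#' vowel-consonant-vowel utterances or dip-bearing noise bands), which is not
#' detectable from the audio alone.
#'
#' @param w A [waveform()].
#' @param b_range Integer vector of boundary channels to evaluate. Default
#'   `20:30` (about 800-1800 Hz on the default grid).
#' @param continuity_eligible Should Continuity be computed? Default `TRUE`.
#' @param target_rms RMS level applied before analysis. Default 0.05.
#' @param floor,edge_frac Passed to [temporal_continuity()]. Defaults
#'   `log(1e-6)` and 0.1.
#' @param ... Passed to [cochleagram()].
#' @return A tibble with one row per boundary: columns `stimulus`, `b`,
#'   `balance`, `continuity` (`NA` when ineligible), `continuity_eligible`.
#' @examples
#' w <- make_noise_band(fc = 600, dip_amp = 0.5, seed = 1)
#' analyze_stimulus(w)
#' @export
analyze_stimulus <- function(w, b_range = 20:30, continuity_eligible = TRUE,
                             target_rms = 0.05, floor = log(1e-6),
                             edge_frac = 0.1, ...) {
  stopifnot(is_waveform(w))
  b_range <- as.integer(b_range)
  if (length(b_range) < 1 || any(is.na(b_range))) {
    abort("`b_range` must be a nonempty integer vector.",
          class = "roundsound_argument_error")
  }
  cg <- cochleagram(normalize_rms(w, target_rms), ...)
  S <- unname(mean_spectrum(cg))
  S <- S * (target_rms^2 / sum(S)) # equate level in the cochlear domain
  bal <- vapply(b_range, function(b) spectral_balance(S, b), numeric(1))
  cont <- NA_real_
  if (isTRUE(continuity_eligible)) {
    cont <- temporal_continuity(frame_energies(cg), floor = floor,
                                edge_frac = edge_frac)
  }
  tibble::tibble(
    stimulus = w$label,
    b = b_range,
    balance = bal,
    continuity = cont,
    continuity_eligible = isTRUE(continuity_eligible)
  )
}

#' Balance and Continuity for a corpus
#'
#' Maps [analyze_stimulus()] over a corpus tibble (as produced by
#' [noise_band_corpus()], [beating_corpus()], [rolling_corpus()], or any tibble
#' with a `stimulus` column and a `wave` list-column) and binds the results
#' into one long tibble.
#'
#' @param corpus A tibble with columns `stimulus` (unique labels) and `wave`
#'   (list of [waveform()] objects). An optional logical column
#'   `continuity_eligible` overrides the argument per stimulus.
#' @param b_range,continuity_eligible,... Passed to [analyze_stimulus()].
#' @return A long tibble: one row per stimulus x boundary.
#' @export
analyze_corpus <- function(corpus, b_range = 20:30, continuity_eligible = TRUE,
                           ...) {
  if (!is.data.frame(corpus) || !all(c("stimulus", "wave") %in% names(corpus))) {
    abort("`corpus` must be a tibble with `stimulus` and `wave` columns.",
          class = "roundsound_argument_error")
  }
  if (anyDuplicated(corpus$stimulus)) {
    abort("Corpus stimulus labels must be unique.",
          class = "roundsound_argument_error")
  }
  eligible <- if ("continuity_eligible" %in% names(corpus)) {
    corpus$continuity_eligible
  } else {
    rep(isTRUE(continuity_eligible), nrow(corpus))
  }
  purrr::map2(corpus$wave, seq_len(nrow(corpus)), function(w, i) {
    w$label <- corpus$stimulus[i]
    analyze_stimulus(w, b_range = b_range,
                     continuity_eligible = eligible[i], ...)
  }) |>
    purrr::list_rbind()
}

#' Pivot long indices to one row per stimulus at a fixed boundary
#'
#' Convenience used by the fitting layer: selects boundary `b` from a long
#' indices tibble and returns `stimulus`, `balance`, `continuity`,
#' `continuity_eligible`.
#'
#' @param indices Long tibble from [analyze_corpus()] / [analyze_stimulus()].
#' @param b Boundary channel to select.
#' @return A tibble with one row per stimulus.
#' @export
indices_at_boundary <- function(indices, b) {
  if (!all(c("stimulus", "b", "balance") %in% names(indices))) {
    abort("`indices` must have columns stimulus, b, balance.",
          class = "roundsound_argument_error")
  }
  out <- dplyr::filter(indices, .data$b == !!b)
  if (nrow(out) == 0) {
    abort(sprintf("Boundary b = %s is not present in `indices`.", b),
          class = "roundsound_argument_error")
  }
  dplyr::select(out, -"b")
}
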