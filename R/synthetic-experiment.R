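#' Generate a synthetic score-recovery experiment
#'
#' Builds a corpus of `n_stimuli` noise bands whose center frequencies are
#' log-spaced across `fc_range` (undipped, so Balance alone drives the
#' scores), computes their Balance at the true boundary `b_true`, and emits
#' round scores that are linear in that Balance -- rescaled to a 0-100 score
#' range -- plus Gaussian noise with standard deviation `noise_sd_frac` of the
#' range. The returned ground truth supports parameter-recovery checks on
#' [scan_boundary()]: the scan should recover `b_true` (within one channel)
#' and the generating Balance slope.
#'
#' The frequency span deliberately straddles the scanned boundary region
#' (roughly 800-1800 Hz) so that fits at different boundaries are
#' distinguishable.
#'
#' @param n_stimuli Number of stimuli. Default 60.
#' @param b_true Generating boundary channel. Default 25.
#' @param noise_sd_frac Score noise SD as a fraction of the score range.
#'   Default 0.05.
#' @param seed Integer seed controlling the noise realizations of the audio
#'   and of the scores.
#' @param fc_range Center-frequency span in Hz. Default `c(300, 3000)`.
#' @param b_range Boundary channels included in the returned indices.
#'   Default `20:30`; must contain `b_true`.
#' @return A list: `corpus` (tibble with `stimulus`, `fc`, `seed`, `wave`),
#'   `indices` (long tibble over `b_range`, ready for [scan_boundary()]),
#'   `scores` (tibble with `stimulus`, `round_score`, `scale_min`,
#'   `scale_max`), `b_true`, `beta_true` (generating Balance slope),
#'   `intercept_true`.
#' @export
synthetic_experiment <- function(n_stimuli = 60, b_true = 25,
                                 noise_sd_frac = 0.05, seed = 1,
                                 fc_range = c(300, 3000), b_range = 20:30) {
  if (!b_true %in% b_range) {
    abort("`b_range` must contain `b_true`.",
          class = "roundsound_argument_error")
  }
  fcs <- exp(seq(log(fc_range[1]), log(fc_range[2]),
                 length.out = n_stimuli))
  seeds <- derive_seeds(seed, n_stimuli + 1)
  corpus <- tibble::tibble(
    stimulus = sprintf("syn_%02d_fc%04.0f", seq_len(n_stimuli), fcs),
    fc = fcs,
    seed = seeds[seq_len(n_stimuli)],
    wave = purrr::pmap(list(fcs, seeds[seq_len(n_stimuli)],
                            sprintf("syn_%02d_fc%04.0f",
                                    seq_len(n_stimuli), fcs)),
                       function(fc, sd, lab) {
                         make_noise_band(fc, dip_amp = 1, seed = sd,
                                         label = lab)
                       })
  )
  idx_long <- analyze_corpus(corpus, b_range = b_range,
                             continuity_eligible = FALSE)
  idx <- indices_at_boundary(idx_long, b_true)
  bal <- idx$balance
  rng <- diff(range(bal))
  beta_true <- 100 / rng
  intercept_true <- -beta_true * min(bal)
  clean <- intercept_true + beta_true * bal
  noise <- withr::with_seed(seeds[n_stimuli + 1],
                            rnorm(n_stimuli, 0, 100 * noise_sd_frac))
  score <- clean + noise
  scores <- tibble::tibble(
    stimulus = idx$stimulus,
    round_score = score,
    scale_min = base::floor(min(score)),
    scale_max = ceiling(max(score))
  )
  list(corpus = corpus, indices = idx_long, scores = scores, b_true = b_true,
       beta_true = beta_true, intercept_true = intercept_true)
}
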