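# Forced-choice respondent simulation and recovery. The generator draws a
# per-participant intercept around a population log-odds and Bernoulli
# responses from a logistic linear predictor; recovery is a fixed-effects
# logistic regression (participant heterogeneity is a robustness dimension of
# the tests, not an estimand here).

#' Specify a simulated respondent population
#'
#' @param intercept Population intercept in log-odds; 0 means round and spiky
#'   choices are equally likely for a zero predictor.
#' @param slopes Named numeric vector of per-predictor log-odds slopes; names
#'   must match predictor columns in the stimulus table.
#' @param participant_sd Between-participant standard deviation of the
#'   intercept, in log-odds (>= 0).
#' @return A list of class `"respondent_model"`.
#' @export
respondent_model <- function(intercept = 0, slopes = numeric(0),
                             participant_sd = 0) {
  check_number(intercept, "intercept")
  check_number(participant_sd, "participant_sd", lower = 0)
  if (length(slopes) > 0 &&
      (is.null(names(slopes)) || any(!nzchar(names(slopes))))) {
    abort("`slopes` must be a named numeric vector.",
          class = "roundsound_argument_error")
  }
  structure(list(intercept = intercept, slopes = slopes,
                 participant_sd = participant_sd),
            class = "respondent_model")
}

#' Trial design for a forced-choice experiment
#'
#' Crosses stimulus labels with repetition indices: the beating-toys design,
#' for instance, presents each of its 30 sounds twice for 60 test trials.
#'
#' @param stimuli Character vector of stimulus labels.
#' @param n_reps Presentations per stimulus. Default 2.
#' @return A tibble with columns `stimulus`, `rep`.
#' @export
trial_design <- function(stimuli, n_reps = 2) {
  if (length(stimuli) < 1 || anyDuplicated(stimuli)) {
    abort("`stimuli` must be a nonempty vector of unique labels.",
          class = "roundsound_argument_error")
  }
  tidyr::expand_grid(stimulus = as.character(stimuli),
                     rep = seq_len(n_reps))
}

#' Simulate forced-choice trials
#'
#' For every participant, an intercept is drawn from the population spread;
#' each (stimulus, repetition) trial then yields a Bernoulli response with
#' probability `plogis(intercept_p + sum(slopes * predictors))`. Responses are
#' coded 1 for a round-shape choice, 0 for a spiky-shape choice.
#'
#' @param stimuli A tibble with a `stimulus` column and one numeric column per
#'   predictor named in `model$slopes` (e.g. output of
#'   [indices_at_boundary()], or a design table).
#' @param model A [respondent_model()].
#' @param n_participants Number of simulated participants (>= 1).
#' @param n_reps Presentations of each stimulus per participant. Default 1.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble: `stimulus`, `participant`, `rep`, the predictor columns,
#'   and `response` (0/1).
#' @export
simulate_trials <- function(stimuli, model, n_participants, n_reps = 1,
                            seed = 1) {
  stopifnot(inherits(model, "respondent_model"))
  if (!is.data.frame(stimuli) || !"stimulus" %in% names(stimuli)) {
    abort("`stimuli` must be a tibble with a `stimulus` column.",
          class = "roundsound_argument_error")
  }
  if (n_participants < 1) {
    abort("`n_participants` must be >= 1.",
          class = "roundsound_argument_error")
  }
  pred_names <- names(model$slopes)
  missing_pred <- setdiff(pred_names, names(stimuli))
  if (length(missing_pred) > 0) {
    abort(sprintf("Predictor column(s) missing from `stimuli`: %s",
                  paste(missing_pred, collapse = ", ")),
          class = "roundsound_argument_error")
  }
  eta_stim <- model$intercept
  if (length(pred_names) > 0) {
    xm <- as.matrix(stimuli[pred_names])
    if (!all(is.finite(xm))) {
      abort("Predictors must be finite.", class = "roundsound_argument_error")
    }
    eta_stim <- model$intercept + as.vector(xm %*% model$slopes)
  } else {
    eta_stim <- rep(model$intercept, nrow(stimuli))
  }

  grid <- tidyr::expand_grid(participant = seq_len(n_participants),
                             stim_idx = seq_len(nrow(stimuli)),
                             rep = seq_len(n_reps))
  withr::with_seed(seed, {
    b0 <- rnorm(n_participants, 0, model$participant_sd)
    eta <- b0[grid$participant] + eta_stim[grid$stim_idx]
    resp <- rbinom(nrow(grid), 1, plogis(eta))
  })
  # carry every scalar design/predictor column of the stimulus table
  carry <- setdiff(names(stimuli)[!vapply(stimuli, is.list, logical(1))],
                   "stimulus")
  out <- dplyr::bind_cols(
    tibble::tibble(stimulus = stimuli$stimulus[grid$stim_idx],
                   participant = grid$participant,
                   rep = grid$rep),
    stimuli[grid$stim_idx, carry, drop = FALSE]
  )
  out$response <- resp
  out
}

#' Aggregate trials into per-stimulus round scores
#'
#' The round score of a stimulus is the percentage of trials on which it was
#' matched to the round shape: `100 * mean(response)` across participants and
#' repetitions. The output feeds [scan_boundary()] directly (scale bounds 0
#' and 100 are attached).
#'
#' @param trials A trial table from [simulate_trials()] (needs `stimulus` and
#'   `response` columns; every stimulus must have at least one trial).
#' @return A tibble: `stimulus`, `round_score`, `n_trials`, `scale_min`,
#'   `scale_max`.
#' @export
aggregate_round_score <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("stimulus", "response") %in% names(trials)) ||
      nrow(trials) == 0) {
    abort("`trials` must be a nonempty table with `stimulus` and `response`.",
          class = "roundsound_argument_error")
  }
  if (!all(trials$response %in% c(0, 1))) {
    abort("Responses must be coded 0 (spiky) or 1 (round).",
          class = "roundsound_argument_error")
  }
  trials |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(round_score = 100 * mean(.data$response),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(scale_min = 0, scale_max = 100)
}

# Perfect-separation screen: a numeric predictor separates the data if some
# threshold on it classifies every response correctly.
find_separating_predictor <- function(trials, predictors) {
  for (p in predictors) {
    x1 <- trials[[p]][trials$response == 1]
    x0 <- trials[[p]][trials$response == 0]
    if (length(x1) == 0 || length(x0) == 0) next
    if (min(x1) > max(x0) || min(x0) > max(x1)) return(p)
  }
  NULL
}

#' Fixed-effects logistic regression on trial data
#'
#' Maximum-likelihood logistic regression of the binary response on the named
#' predictors, with Wald standard errors. Both response classes must occur and
#' no predictor may perfectly separate them.
#'
#' @param trials A trial table (see [simulate_trials()]).
#' @param predictors Character vector of predictor column names.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`.
#' @export
fit_choice_glm <- function(trials, predictors) {
  if (!is.data.frame(trials) || !"response" %in% names(trials)) {
    abort("`trials` must contain a `response` column.",
          class = "roundsound_argument_error")
  }
  missing_pred <- setdiff(predictors, names(trials))
  if (length(missing_pred) > 0) {
    abort(sprintf("Predictor column(s) missing from `trials`: %s",
                  paste(missing_pred, collapse = ", ")),
          class = "roundsound_argument_error")
  }
  if (length(unique(trials$response)) < 2) {
    abort("Both response classes (0 and 1) must be present.",
          class = "roundsound_argument_error")
  }
  sep <- find_separating_predictor(trials, predictors)
  if (!is.null(sep)) {
    abort(sprintf("Perfect separation: predictor '%s' fully separates the responses.",
                  sep),
          class = "roundsound_separation_error")
  }
  fml <- stats::reformulate(predictors, response = "response")
  m <- glm(fml, family = binomial(), data = trials)
  sm <- summary(m)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "z value"]),
    p.value = unname(sm[, "Pr(>|z|)"])
  )
}
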