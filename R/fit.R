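# Linear roundness model: round scores regressed on Balance (and Continuity
# when available), with an exhaustive scan of the boundary channel b.

validate_scores <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("stimulus", "round_score") %in% names(scores))) {
    abort("`scores` must have columns `stimulus` and `round_score`.",
          class = "roundsound_argument_error")
  }
  if (anyDuplicated(scores$stimulus)) {
    abort("Score table stimulus labels must be unique.",
          class = "roundsound_argument_error")
  }
  if (nrow(scores) < 3) {
    abort("At least 3 stimuli are required for a fit.",
          class = "roundsound_argument_error")
  }
  if (all(c("scale_min", "scale_max") %in% names(scores))) {
    bad <- scores$round_score < scores$scale_min |
      scores$round_score > scores$scale_max
    if (any(bad)) {
      abort(sprintf("Round scores outside [scale_min, scale_max] for: %s",
                    paste(scores$stimulus[bad], collapse = ", ")),
            class = "roundsound_argument_error")
    }
  }
  invisible(scores)
}

# r2 / t / p convention: r2 is the squared correlation between fitted and
# observed scores; t and p come from the slope test of the simple regression
# of observed on fitted values. Degenerate cases (constant observed or fitted
# values) report r2 = 0, p = 1 rather than NA.
fit_statistics <- function(observed, fitted_vals) {
  if (sd(observed) == 0 || sd(fitted_vals) == 0) {
    return(list(r2 = 0, t_stat = 0, p_value = 1))
  }
  m <- lm(observed ~ fitted_vals)
  # summary.lm warns on an exactly perfect fit; the slope test is still the
  # contracted output (t -> Inf, p -> 0)
  sm <- suppressWarnings(summary(m))$coefficients
  list(r2 = cor(fitted_vals, observed)^2,
       t_stat = unname(sm[2, "t value"]),
       p_value = unname(sm[2, "Pr(>|t|)"]))
}

#' Fit round scores from Balance (and Continuity) at one boundary
#'
#' Ordinary least squares of the experimental round score on the Balance index
#' and, when available and eligible, the Continuity index. Scores are fitted on
#' each study's native scale; predictors are not standardized.
#'
#' @param indices Per-stimulus tibble with columns `stimulus`, `balance`, and
#'   optionally `continuity` (see [indices_at_boundary()]).
#' @param scores Tibble with columns `stimulus`, `round_score`, and optionally
#'   `scale_min`, `scale_max` (scores are validated against the bounds).
#' @param use_continuity Include Continuity as a predictor? Default `TRUE`
#'   when a complete `continuity` column is present.
#' @return A list: `coefficients` (named: `(Intercept)`, `balance`,
#'   `continuity` if used), `r2`, `t_stat`, `p_value`, `predictions` tibble
#'   (`stimulus`, `observed`, `predicted`), `model` (the `lm` fit), and
#'   `continuity_used`.
#' @export
fit_round_scores <- function(indices, scores,
                             use_continuity = NULL) {
  validate_scores(scores)
  if (!all(c("stimulus", "balance") %in% names(indices))) {
    abort("`indices` must have columns `stimulus` and `balance`.",
          class = "roundsound_argument_error")
  }
  unmatched <- setdiff(scores$stimulus, indices$stimulus)
  if (length(unmatched) > 0) {
    abort(sprintf("Score table stimuli missing from the indices: %s",
                  paste(unmatched, collapse = ", ")),
          class = "roundsound_argument_error")
  }
  df <- dplyr::inner_join(scores, indices, by = "stimulus")
  if (nrow(df) < 3) {
    abort("At least 3 matched stimuli are required for a fit.",
          class = "roundsound_argument_error")
  }
  have_cont <- "continuity" %in% names(df) && !anyNA(df$continuity)
  use_continuity <- use_continuity %||% have_cont
  if (use_continuity && !have_cont) {
    abort("Continuity requested but missing (or NA) for some stimuli.",
          class = "roundsound_argument_error")
  }

  predictors <- c("balance", if (use_continuity) "continuity")
  const <- predictors[vapply(predictors, function(p) sd(df[[p]]) == 0,
                             logical(1))]
  if (length(const) > 0) {
    abort(sprintf("Rank-deficient design: constant predictor(s): %s",
                  paste(const, collapse = ", ")),
          class = "roundsound_rank_error")
  }

  fml <- stats::reformulate(predictors, response = "round_score")
  m <- lm(fml, data = df)
  stats <- fit_statistics(df$round_score, unname(stats::fitted(m)))

  list(
    coefficients = coef(m),
    r2 = stats$r2,
    t_stat = stats$t_stat,
    p_value = stats$p_value,
    predictions = tibble::tibble(
      stimulus = df$stimulus,
      observed = df$round_score,
      predicted = unname(stats::fitted(m))
    ),
    model = m,
    continuity_used = use_continuity
  )
}

#' Scan the Balance boundary and keep the best-fitting model
#'
#' Fits the roundness model at every boundary channel in `b_range` and returns
#' the fit with maximal explained variance r2, ties broken toward the smallest
#' boundary. The scan is exhaustive; with the default range it costs 11 OLS
#' fits.
#'
#' @param x Either a corpus tibble (with `stimulus` and `wave` columns; it is
#'   analyzed with [analyze_corpus()]) or a long indices tibble already holding
#'   `stimulus`, `b`, `balance` (and optionally `continuity`).
#' @param scores Score table as in [fit_round_scores()].
#' @param b_range Boundary channels to scan. Default `20:30`.
#' @param continuity `"auto"` (use Continuity whenever complete), `"on"`
#'   (require it), or `"off"`.
#' @param ... Passed to [analyze_corpus()] when `x` is a corpus.
#' @return An object of class `"roundness_fit"`: the selected boundary
#'   `b_star`, `coefficients`, `r2`, `t_stat`, `p_value`, `predictions`,
#'   `r2_by_b` (tibble of the scan curve), `continuity_used`, and the
#'   underlying `lm` in `model`. Supports [tidy()], [glance()], [predict()],
#'   [autoplot()].
#' @examples
#' \donttest{
#' corpus <- noise_band_corpus(master_seed = 1)
#' idx <- analyze_corpus(corpus)
#' scores <- tibble::tibble(
#'   stimulus = corpus$stimulus,
#'   round_score = 50 + 10 * scale(dplyr::filter(idx, b == 25)$balance)[, 1]
#' )
#' fit <- scan_boundary(idx, scores)
#' glance(fit)
#' }
#' @export
scan_boundary <- function(x, scores, b_range = 20:30,
                          continuity = c("auto", "on", "off"), ...) {
  continuity <- match.arg(continuity)
  indices <- if ("wave" %in% names(x)) {
    analyze_corpus(x, b_range = b_range, ...)
  } else {
    x
  }
  if (!all(c("stimulus", "b", "balance") %in% names(indices))) {
    abort("`x` must be a corpus or a long indices tibble (stimulus, b, balance).",
          class = "roundsound_argument_error")
  }
  b_range <- as.integer(b_range)
  missing_b <- setdiff(b_range, unique(indices$b))
  if (length(missing_b) > 0) {
    abort(sprintf("Indices lack boundaries: %s",
                  paste(missing_b, collapse = ", ")),
          class = "roundsound_argument_error")
  }
  use_cont <- switch(continuity,
    on = TRUE,
    off = FALSE,
    auto = "continuity" %in% names(indices) && !anyNA(indices$continuity)
  )

  fits <- lapply(b_range, function(b) {
    fit_round_scores(indices_at_boundary(indices, b), scores,
                     use_continuity = use_cont)
  })
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  best <- which.max(r2s) # first maximum: ties break toward smallest b

  out <- fits[[best]]
  out$b_star <- b_range[best]
  out$r2_by_b <- tibble::tibble(b = b_range, r2 = r2s)
  class(out) <- "roundness_fit"
  out
}

#' @export
print.roundness_fit <- function(x, ...) {
  cat(sprintf("<roundness_fit> b* = %d, r2 = %.3f (t = %.2f, p = %.3g)\n",
              x$b_star, x$r2, x$t_stat, x$p_value))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname scan_boundary
#' @param object,x A `"roundness_fit"`.
#' @export
tidy.roundness_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname scan_boundary
#' @export
glance.roundness_fit <- function(x, ...) {
  tibble::tibble(
    b_star = x$b_star,
    r2 = x$r2,
    t_stat = x$t_stat,
    p_value = x$p_value,
    nobs = nrow(x$predictions),
    continuity_used = x$continuity_used
  )
}

#' Predict round scores from a fitted model
#'
#' Applies the fitted intercept and slopes to new per-stimulus indices. The
#' indices must cover the fitted boundary `b_star` and, when the model used
#' Continuity, provide a complete `continuity` column.
#'
#' @param object A `"roundness_fit"` from [scan_boundary()].
#' @param newdata A long indices tibble (with a `b` column) or a per-stimulus
#'   tibble already at `b_star`.
#' @param ... Unused.
#' @return A tibble with columns `stimulus`, `predicted`.
#' @export
predict.roundness_fit <- function(object, newdata, ...) {
  idx <- if ("b" %in% names(newdata)) {
    indices_at_boundary(newdata, object$b_star)
  } else {
    newdata
  }
  if (!all(c("stimulus", "balance") %in% names(idx))) {
    abort("`newdata` must provide `stimulus` and `balance`.",
          class = "roundsound_argument_error")
  }
  pred <- object$coefficients[["(Intercept)"]] +
    object$coefficients[["balance"]] * idx$balance
  if (object$continuity_used) {
    if (!"continuity" %in% names(idx) || anyNA(idx$continuity)) {
      abort("Model was fitted with Continuity but `newdata` lacks complete continuity values.",
            class = "roundsound_argument_error")
    }
    pred <- pred + object$coefficients[["continuity"]] * idx$continuity
  }
  tibble::tibble(stimulus = idx$stimulus, predicted = unname(pred))
}

#' @rdname scan_boundary
#' @export
autoplot.roundness_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue") +
    ggplot2::labs(
      x = "Experimental round score",
      y = "Predicted round score",
      title = sprintf("b* = %d, r2 = %.2f", object$b_star, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the boundary-scan curve
#'
#' Explained variance r2 as a function of the boundary channel, with the
#' selected boundary marked.
#'
#' @param fit A `"roundness_fit"`.
#' @return A ggplot object.
#' @export
plot_scan_curve <- function(fit) {
  stopifnot(inherits(fit, "roundness_fit"))
  ggplot2::ggplot(fit$r2_by_b, ggplot2::aes(x = .data$b, y = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$b_star, linetype = "dashed",
                        color = "steelblue") +
    ggplot2::labs(x = "Boundary channel b", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
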