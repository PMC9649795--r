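# A small deterministic indices/scores pair used across fitting tests.
toy_indices <- function(balance = c(-2, -1, 0, 1, 2),
                        continuity = NULL) {
  out <- tibble::tibble(
    stimulus = paste0("s", seq_along(balance)),
    balance = balance
  )
  if (!is.null(continuity)) out$continuity <- continuity
  out
}

test_that("noise-free linear scores are fitted perfectly", {
  idx <- toy_indices()
  scores <- tibble::tibble(stimulus = idx$stimulus,
                           round_score = 3 * idx$balance + 10)
  fit <- fit_round_scores(idx, scores)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), c(10, 3), tolerance = 1e-9)
  expect_equal(fit$predictions$predicted, scores$round_score,
               tolerance = 1e-9)
})

test_that("constant scores report zero explained variance, p = 1", {
  idx <- toy_indices()
  scores <- tibble::tibble(stimulus = idx$stimulus, round_score = rep(5, 5))
  fit <- fit_round_scores(idx, scores)
  expect_equal(fit$r2, 0)
  expect_equal(fit$p_value, 1)
})

test_that("OLS coefficients match the normal-equations oracle", {
  idx <- toy_indices()
  scores <- tibble::tibble(
    stimulus = idx$stimulus,
    round_score = 2 * idx$balance + 1 + c(0.1, -0.1, 0, 0.1, -0.1)
  )
  fit <- fit_round_scores(idx, scores)
  X <- cbind(1, idx$balance)
  oracle <- solve(crossprod(X), crossprod(X, scores$round_score))
  expect_equal(unname(fit$coefficients), as.vector(oracle), tolerance = 1e-9)

  # two predictors
  idx2 <- toy_indices(continuity = c(-3, -1, -2, 0, -0.5))
  scores2 <- tibble::tibble(
    stimulus = idx2$stimulus,
    round_score = 1 + 2 * idx2$balance - 4 * idx2$continuity +
      c(0.2, -0.1, 0, 0.1, -0.2)
  )
  fit2 <- fit_round_scores(idx2, scores2)
  X2 <- cbind(1, idx2$balance, idx2$continuity)
  oracle2 <- solve(crossprod(X2), crossprod(X2, scores2$round_score))
  expect_equal(unname(fit2$coefficients), as.vector(oracle2),
               tolerance = 1e-9)
})

test_that("degenerate designs and tables are rejected", {
  idx <- toy_indices(balance = rep(1, 5))
  scores <- tibble::tibble(stimulus = idx$stimulus, round_score = 1:5)
  expect_error(fit_round_scores(idx, scores), class = "roundsound_rank_error")

  small <- toy_indices(balance = c(1, 2))
  expect_error(
    fit_round_scores(small, tibble::tibble(stimulus = small$stimulus,
                                           round_score = c(1, 2))),
    class = "roundsound_argument_error")

  # unmatched labels are listed by name
  idx5 <- toy_indices()
  bad <- tibble::tibble(stimulus = c(idx5$stimulus[1:4], "ghost"),
                        round_score = 1:5)
  expect_error(fit_round_scores(idx5, bad), "ghost")

  # out-of-bounds scores
  oob <- tibble::tibble(stimulus = idx5$stimulus, round_score = c(1, 2, 3, 4, 150),
                        scale_min = 0, scale_max = 100)
  expect_error(fit_round_scores(idx5, oob), class = "roundsound_argument_error")
})

long_toy_indices <- function(bals) {
  purrr::list_rbind(purrr::imap(bals, function(v, b) {
    tibble::tibble(stimulus = paste0("s", seq_along(v)),
                   b = as.integer(b), balance = v)
  }))
}

test_that("boundary scan maximizes r2 and breaks ties toward smaller b", {
  scores <- tibble::tibble(stimulus = paste0("s", 1:5),
                           round_score = c(2, 4, 5, 7, 12))
  # b = 25 is exactly linear with the scores; the others are noisy variants
  bals <- list(`24` = c(1, 3, 2, 4, 5), `25` = c(1, 2, 2.5, 3.5, 6),
               `26` = c(2, 1, 3, 5, 4))
  idx <- long_toy_indices(bals)
  fit <- scan_boundary(idx, scores, b_range = 24:26)
  expect_equal(fit$b_star, 25)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(max(fit$r2_by_b$r2), fit$r2)
  expect_true(all(fit$r2 >= fit$r2_by_b$r2))

  # single-boundary scan returns that boundary
  one <- scan_boundary(dplyr::filter(idx, b == 24), scores, b_range = 24)
  expect_equal(one$b_star, 24)

  # duplicated balance column gives bitwise-equal r2: smaller b wins
  dup <- long_toy_indices(list(`24` = c(1, 3, 2, 4, 5),
                               `25` = c(1, 3, 2, 4, 5)))
  tie <- scan_boundary(dup, scores, b_range = 24:25)
  expect_equal(tie$b_star, 24)
})

test_that("prediction reproduces fitted values and validates eligibility", {
  idx <- long_toy_indices(list(`25` = c(-2, -1, 0, 1, 2)))
  idx$continuity <- c(-1, -2, -0.5, -3, -1.5)
  scores <- tibble::tibble(stimulus = paste0("s", 1:5),
                           round_score = c(10, 8, 20, 2, 15))
  fit <- scan_boundary(idx, scores, b_range = 25, continuity = "on")
  expect_true(fit$continuity_used)

  pred <- predict(fit, idx)
  expect_equal(pred$predicted, fit$predictions$predicted, tolerance = 1e-12)

  bare <- dplyr::select(idx, -"continuity")
  expect_error(predict(fit, bare), class = "roundsound_argument_error")

  # balance-only fallback has exactly intercept + balance
  fit0 <- scan_boundary(dplyr::select(idx, -"continuity"), scores,
                        b_range = 25, continuity = "off")
  expect_named(fit0$coefficients, c("(Intercept)", "balance"))
})

test_that("broom and plotting methods expose the fit", {
  idx <- long_toy_indices(list(`25` = c(-2, -1, 0, 1, 2)))
  scores <- tibble::tibble(stimulus = paste0("s", 1:5),
                           round_score = c(1, 4, 4, 8, 9))
  fit <- scan_boundary(idx, scores, b_range = 25)
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "balance"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 5)
  expect_true(gl$r2 >= 0 && gl$r2 <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_scan_curve(fit), "ggplot")
})

test_that("the scan recovers the generating boundary and slope", {
  res <- vapply(1:2, function(s) {
    ex <- synthetic_experiment(n_stimuli = 30, seed = s)
    fit <- scan_boundary(ex$indices, ex$scores, continuity = "off")
    c(fit$b_star, fit$coefficients[["balance"]], ex$beta_true)
  }, numeric(3))
  expect_true(all(abs(res[1, ] - 25) <= 1))
  expect_lt(mean(abs(res[2, ] - res[3, ]) / res[3, ]), 0.1)
})
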