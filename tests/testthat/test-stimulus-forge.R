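segment_rms <- function(w, t0, t1) {
  i <- seq(max(1, round(t0 * w$fs) + 1), round(t1 * w$fs))
  sqrt(mean(w$samples[i]^2))
}

test_that("noise bands honor the dip contract", {
  flat <- make_noise_band(fc = 600, dip_amp = 1, seed = 5)
  expect_equal(length(flat$samples), 22050)
  expect_equal(flat$fs, 44100)
  dip_rms <- segment_rms(flat, 0.230, 0.270)
  flank_rms <- segment_rms(flat, 0.05, 0.20)
  expect_lt(abs(dip_rms - flank_rms) / flank_rms, 0.2)

  silent <- make_noise_band(fc = 600, dip_amp = 0, seed = 5)
  core <- silent$samples[round(0.230 * 44100):round(0.270 * 44100)]
  expect_true(all(core == 0)) # digital silence inside the dip

  half <- make_noise_band(fc = 600, dip_amp = 0.5, seed = 5)
  expect_equal(segment_rms(half, 0.230, 0.270) / segment_rms(half, 0.05, 0.2),
               0.5, tolerance = 0.2)
})

test_that("noise bands concentrate energy at the requested frequency", {
  w <- make_noise_band(fc = 600, dip_amp = 1, seed = 8)
  expect_lt(abs(welch_peak_hz(w, seg = 4096) - 600), 60)
  w2 <- make_noise_band(fc = 1000, dip_amp = 1, seed = 8)
  expect_lt(abs(welch_peak_hz(w2, seg = 4096) - 1000), 100)
})

test_that("the noise-band corpus is the seeded 8 x 4 factorial", {
  corpus <- noise_band_corpus(master_seed = 3)
  expect_equal(nrow(corpus), 32)
  expect_equal(length(unique(corpus$fc)), 8)
  expect_equal(as.integer(table(corpus$dip_amp)), rep(8L, 4))
  expect_false(anyDuplicated(corpus$stimulus) > 0)
  expect_false(anyDuplicated(corpus$seed) > 0)

  again <- noise_band_corpus(master_seed = 3)
  expect_identical(purrr::map(corpus$wave, "samples"),
                   purrr::map(again$wave, "samples"))
  other <- noise_band_corpus(master_seed = 4)
  expect_false(identical(corpus$wave[[1]]$samples, other$wave[[1]]$samples))
})

test_that("Weyl mode frequencies order by perimeter and area", {
  area <- 1
  p_disk <- 2 * sqrt(pi * area)
  f_disk <- weyl_modes(area, p_disk, 10)
  expect_true(all(diff(f_disk) > 0))
  expect_true(all(f_disk > 0))

  f_spiky <- weyl_modes(area, 1.6 * p_disk, 10)
  expect_true(all(f_spiky >= f_disk))
  expect_gt(mean(f_spiky), mean(f_disk))

  f_big <- weyl_modes(2 * area, 2 * sqrt(pi * 2 * area), 10)
  expect_lt(f_big[1], f_disk[1])

  # the disk attains the minimum mean mode frequency at its area
  for (fac in c(1.1, 1.4, 2)) {
    expect_gt(mean(weyl_modes(area, fac * p_disk, 10)), mean(f_disk))
  }
  expect_error(weyl_modes(area, 0.9 * p_disk, 10),
               class = "roundsound_argument_error")
})

test_that("impact sounds decay and carry the shape contrast", {
  w <- synth_impact(1, 2 * sqrt(pi), seed = 2)
  expect_gte(wave_duration(w), 0.200)
  expect_lte(wave_duration(w), 0.220)
  expect_equal(wave_rms(w), 0.05, tolerance = 1e-9)

  slow <- synth_impact(1, 2 * sqrt(pi), damping = 6, duration = 0.21, seed = 2)
  fast <- synth_impact(1, 2 * sqrt(pi), damping = 30, duration = 0.21, seed = 2)
  late <- function(w) segment_rms(w, 0.095, 0.125) / segment_rms(w, 0, 0.03)
  expect_lt(late(fast), late(slow))

  round_w <- synth_impact(1, 2 * sqrt(pi), seed = 3, label = "round")
  spiky_w <- synth_impact(1, 1.6 * 2 * sqrt(pi), seed = 3, label = "spiky")
  ib <- function(w) {
    idx <- analyze_stimulus(w, b_range = 25, continuity_eligible = FALSE)
    idx$balance
  }
  expect_gt(ib(round_w), ib(spiky_w))
})

test_that("the beating corpus is balanced and spectrally signed", {
  corpus <- beating_corpus(master_seed = 2)
  expect_equal(nrow(corpus), 30)
  expect_equal(as.integer(table(corpus$shape)), c(15L, 15L))
  expect_equal(length(unique(corpus$object)), 10)

  # spot-check the band-energy signature on one member per class
  w_round <- corpus$wave[[which(corpus$shape == "round")[1]]]
  w_spiky <- corpus$wave[[which(corpus$shape == "spiky")[1]]]
  expect_gt(band_energy(w_round, 0, 500), band_energy(w_round, 500, 2000))
  expect_gt(band_energy(w_spiky, 500, 2000), band_energy(w_spiky, 0, 500))

  again <- beating_corpus(master_seed = 2)
  expect_identical(purrr::map(corpus$wave, "samples"),
                   purrr::map(again$wave, "samples"))
})

test_that("envelope extraction is smooth, prompt, and linear", {
  noise <- white_noise_wave(0.5, seed = 6)
  env <- extract_envelope(noise)
  expect_true(all(env$values >= 0))
  interior <- env$values[50:450]
  expect_lt(sd(interior) / mean(interior), 0.1)

  # amplitude step 0.1 -> 1.0: envelope rises monotonically through the
  # transition and settles within 31 ms
  n <- 22050
  step <- waveform(withr::with_seed(1, rnorm(2 * n)) * rep(c(0.1, 1), each = n),
                   44100)
  senv <- extract_envelope(step)
  t_mid <- n / 44100
  win <- senv$values[abs((seq_along(senv$values) - 1) / senv$rate - t_mid) <= 0.0155]
  expect_true(all(diff(win) > 0))

  env2 <- extract_envelope(waveform(2 * noise$samples, noise$fs))
  expect_equal(env2$values, 2 * env$values, tolerance = 1e-9)
})

test_that("shaped noise matches its target profile within 3 dB", {
  flat <- rep(1e-5, 64)
  w <- shaped_noise(flat, duration = 0.5, seed = 4)
  measured <- unname(mean_spectrum(cochleagram(w)))
  qual <- flat >= 0.01 * sum(flat)
  err_db <- 10 * log10(measured[qual] / flat[qual])
  expect_lt(max(abs(err_db)), 3)

  # profile taken from a round impact: Balance sign carries over
  src <- synth_impact(1.2, 2 * sqrt(pi * 1.2), seed = 9)
  prof <- unname(mean_spectrum(cochleagram(normalize_rms(src))))
  shaped <- shaped_noise(prof, duration = 0.3, seed = 5)
  bal_src <- spectral_balance(prof, 25)
  bal_out <- spectral_balance(unname(mean_spectrum(cochleagram(shaped))), 25)
  expect_equal(sign(bal_out), sign(bal_src))

  expect_identical(shaped_noise(flat, 0.3, seed = 7)$samples,
                   shaped_noise(flat, 0.3, seed = 7)$samples)
  expect_error(shaped_noise(rep(0, 64), 0.3),
               class = "roundsound_degenerate_input_error")
})

test_that("envelope transplantation modulates, normalizes, and validates", {
  carrier <- white_noise_wave(0.3, seed = 3)
  const <- envelope(rep(1, 200), 1000)
  out <- transplant_envelope(const, carrier)
  expect_equal(wave_duration(out), 0.2, tolerance = 1e-3)
  prefix <- normalize_rms(waveform(carrier$samples[seq_along(out$samples)],
                                   carrier$fs))
  expect_equal(out$samples, prefix$samples, tolerance = 1e-9)

  smooth_env <- extract_envelope(make_rolling("smooth", seed = 2))
  sharp_env <- extract_envelope(make_rolling("sharp", seed = 2))
  cont <- function(w) analyze_stimulus(w, b_range = 25)$continuity
  expect_gt(cont(transplant_envelope(smooth_env, carrier)),
            cont(transplant_envelope(sharp_env, carrier)))

  expect_error(transplant_envelope(envelope(rep(0, 100), 1000), carrier),
               class = "roundsound_degenerate_input_error")
  long_env <- envelope(rep(1, 500), 1000)
  expect_error(transplant_envelope(long_env, carrier),
               class = "roundsound_argument_error")
})

test_that("rolling envelopes meet the printed dB constraints", {
  smooth <- make_rolling("smooth", "wood", seed = 4)
  sharp <- make_rolling("sharp", "plastic", seed = 4)
  expect_lt(envelope_swing_db(extract_envelope(smooth), Inf), 6)
  expect_gt(envelope_swing_db(extract_envelope(sharp), 0.035), 8)
})

test_that("the rolling corpus crosses envelope and carrier as designed", {
  corpus <- rolling_corpus(master_seed = 5)
  expect_equal(nrow(corpus), 36)
  expect_equal(sum(corpus$type == "original"), 12)
  expect_equal(sum(corpus$type == "synthetic"), 24)

  synth <- dplyr::filter(corpus, type == "synthetic")
  cells <- dplyr::count(synth, envelope_shape, carrier)
  expect_equal(nrow(cells), 4)
  expect_true(all(cells$n == 6))

  again <- rolling_corpus(master_seed = 5)
  expect_identical(purrr::map(corpus$wave, "samples"),
                   purrr::map(again$wave, "samples"))
})
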