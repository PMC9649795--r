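---
title: "The Balance x Continuity model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Balance x Continuity model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science inside `roundsound`: the model, its
assumptions, the synthesis machinery behind the built-in stimulus corpora,
and the design decisions taken where the underlying method left the choice
open. It states no empirical result that the package's tests do not
themselves compute.

## The phenomenological model

The bouba-kiki effect is the cross-modal tendency to match certain sounds to
round shapes and others to spiky shapes. The model implemented here predicts
a per-stimulus *round score* — the proportion of round-shape choices in a
two-alternative forced-choice task — from exactly two acoustic quantities,
both computed on a gammatone cochleagram:

* **Balance**: the summed mean-spectrum energy below a boundary channel $b$
  minus the summed energy above it,
  $\mathrm{Balance}(b) = \sum_{i \le b} S_i - \sum_{i > b} S_i$.
  Spectrally low sounds (back vowels, large resonant objects) score positive.
* **Continuity**: the log ratio of the minimum to the maximum summed frame
  energy, $\log(\min_t E_t / \max_t E_t)$. A flat amplitude envelope scores
  0; an interior dip (an intervocalic consonant, a rattling contact) scores
  strongly negative.

Round scores are then fitted by ordinary least squares on Balance and — for
stimuli whose envelope can meaningfully contain an interior dip — Continuity.
The boundary $b$ is not estimated from audio: all integer channels from 20 to
30 (about 800–1800 Hz on the default grid) are fitted exhaustively and the
boundary with maximal explained variance $r^2$ is kept, ties broken toward
the smaller channel for determinism.

The model is deliberately phenomenological. It assumes (i) that the two
indices capture the dominant acoustic covariates of roundness judgements,
(ii) that their combination is linear on each study's native score scale, and
(iii) that the stimulus set has been equated in intensity so that an energy
*difference* (Balance) is comparable across stimuli. None of these are claims
about mechanism; they are the minimal reading of the judgement data.

## The auditory front end

The filterbank is a 4th-order gammatone (four cascaded biquads per channel,
Slaney-style coefficients) with Glasberg–Moore ERB bandwidths,
$\mathrm{ERB}(f) = 24.7\,(4.37 f/1000 + 1)$ Hz. The 64 center frequencies are
uniform on the ERB-rate scale $21.4 \log_{10}(0.00437 f + 1)$ with inclusive
endpoints 50 and 20,000 Hz; that convention places channel 20 near 800 Hz and
channel 30 near 1800 Hz, which is precisely the scanned boundary region, and
is validated against those two anchors in the tests rather than asserted as
the only possible convention. Because the top channel sits at 20 kHz, all
analysis requires a sampling rate of at least 40 kHz; the canonical internal
rate is 44,100 Hz and loaders resample on ingest.

Frame energies are squared filter outputs averaged in 20 ms rectangular
frames with a 10 ms hop. Neither value is dictated by the model; 20 ms is
short enough to resolve a 50 ms amplitude dip with at least two interior
frames and long enough to average over the carrier fine structure. Energies
stay on a linear power scale throughout — Balance sums them and Continuity
takes a ratio, so dB compression would silently change the model.

Filtering is implemented by evaluating the biquad-cascade transfer function
on a zero-padded DFT grid (pad ≥ 0.1 s, past the slowest channel's ring-out).
This is numerically equivalent to running the IIR recursion and considerably
faster in R, which matters because the recovery simulations below analyze
thousands of half-second stimuli.

### Intensity normalization

Stimuli are RMS-normalized (target 0.05) and, in addition, the mean spectrum
is rescaled so that its total energy is identical for every stimulus
(`target_rms^2`). The second step is the package's reading of
"normalized in terms of intensity": Balance is a *difference* of energies, so
level must be equated in the representation in which the difference is taken.
Waveform RMS alone is not sufficient — the filterbank's summed power response
varies by a few tenths of a percent across center frequency, and for
narrowband stimuli far below the boundary that residual level difference is
larger than the true high-band tail, which would make Balance non-monotone in
center frequency for reasons that have nothing to do with spectral balance.
Continuity, a ratio, is invariant to both scalings.

## Numerical choices and degenerate inputs

* **Log base in Continuity**: natural log. Any base rescales the index by a
  positive constant that the regression slope absorbs; only reported
  magnitudes change.
* **Silence floor**: Continuity is clamped below at $\log(10^{-6}) \approx
  -13.8$. A stimulus with a digitally silent interior interval has ratio 0
  and log $-\infty$, which would break the regression; the floor keeps such
  stimuli usable and ordered below every non-silent one.
* **Interior minimum**: the first and last 10% of frames are excluded from
  the minimum search (the maximum uses all frames). Onset/offset ramps would
  otherwise masquerade as interior dips. Whether the original analyses did
  this is not documented; it is this package's decision and is flagged as
  such.
* **Eligibility is metadata**: Continuity is only computed when the caller
  says the stimulus class supports it (dip-bearing noise bands,
  vowel–consonant–vowel utterances). It is not detectable from audio alone,
  so it is a flag, not an inference.
* **Degenerate fits**: a constant observed score or constant fitted value
  yields $r^2 = 0$ and $p = 1$ by contract instead of `NA`; constant
  predictors raise a rank-deficiency error; score tables are validated
  against their declared scale bounds and for unmatched labels.
* **$t$ and $p$ of a fit** are taken from the slope test of the simple
  regression of observed on fitted scores. With several reasonable
  conventions available, this is the most direct reading of per-experiment
  scatterplot regressions, and it is applied uniformly.

## The stimulus forge

The generators' defaults are the study conditions of the experiments they
emulate, not tuning knobs.

**Noise bands.** White noise through a two-pole resonator (bandwidth =
fc/10), 500 ms at 44,100 Hz, amplitude 1 except a dip at 225–275 ms with
relative amplitude 0, 0.1, 0.5 or 1. Ramps (5 ms at the edges, 2 ms into the
dip) are this package's addition: the dip and onset would otherwise click,
contaminating Balance with broadband splatter. The corpus is the full 8 × 4
factorial, 32 stimuli, one seeded noise realization each.

**Impact sounds.** The two-term Weyl counting law for a vibrating membrane,
$N(f) = (\pi A/c^2) f^2 - (P/2c) f$, is inverted at $N = 1..40$ to give mode
frequencies for a shape of area $A$ and perimeter $P$: at fixed area, modes
rise with perimeter, and the disk (isoperimetric minimum) rings lowest. The
wave-speed constant is calibrated so a unit-area disk's fundamental is 220 Hz
— a typical pitch for a fist-sized struck object. Sounds are sums of damped
sinusoids (damping grows with frequency), 200–220 ms, with seeded phases and
sub-percent frequency jitter between repeated strikes. Mode amplitudes follow
the shape's isoperimetric ratio: compact shapes get a $1/k$ low-emphasis
excitation, spiky shapes a high-pass contact excitation — striking a point
concentrates energy into higher modes. With these constants, every round
corpus member carries more cochlear energy below 500 Hz than in 500–2000 Hz
and every spiky member the reverse; the corpus is 5 round + 5 spiky objects
(areas 0.6–1.5, spiky perimeter factors 1.4–1.8) × 3 strikes = 30 sounds.

**Rolling sounds.** Broadband noise with a first-order spectral emphasis (low
for smooth contours, high for sharp ones; the surface preset adds a mild
tilt, wood darker than plastic) under an envelope that encodes the contour:
smooth rolls modulate gently (a few Hz, total swing about 2 dB, under the
6 dB / 40 ms constraint), sharp rolls contain three brief notches (5 ms fall,
10 ms floor at −16.5 dB, 5 ms rise), exceeding 8 dB within less than 40 ms.
The corpus is 2 shapes × 2 surfaces × 3 instances = 12 originals; each
original's envelope is then transplanted onto two spectrum-matched noise
carriers (one shaped to the smooth-class mean spectrum, one to the
sharp-class), giving 24 synthetic stimuli that fully cross envelope shape
with spectral balance.

**Envelope machinery.** Envelopes are full-wave rectification smoothed by a
Hann kernel of width 1/32 s, decimated to 1 kHz. A windowed kernel has a
monotone step response — no ringing to fake an envelope dip — and 32 Hz
preserves the 40 ms-scale fluctuations the rolling constraints quantify. The
original envelope-extraction algorithm behind the constraint figures is not
documented; this implementation is a declared stand-in with the properties
the analyses need (smoothness, promptness, linearity in gain). Spectrum
matching in `shaped_noise()` is analysis–resynthesis: frequency-domain
shaping iterated against the package's own cochleagram until every channel
holding at least 1% of target energy agrees within 3 dB.

## Respondent simulation

`simulate_trials()` draws per-participant intercepts from a normal spread and
Bernoulli responses through a logistic link; `fit_choice_glm()` recovers
fixed effects by maximum likelihood with Wald standard errors. Mixed-effects
estimation is deliberately out of scope: the generator's `participant_sd` is
a robustness dimension for the tests, not an estimand. One consequence,
verified in simulation design: with heterogeneity present and ignored, Wald
type-I error on between-participant-constant predictors is inflated, so the
calibration check (rejection rate within [2.5%, 7.5%] at 400 replicates) is
run at `participant_sd = 0`, which is the null it actually tests. Perfect
separation is screened per predictor before fitting and reported by name.

## What the synthetic corpora do and do not show

The generators emulate the *designs* of the judgement experiments — their
factorial structure, durations, spectral orderings, envelope constraints, and
trial counts — with seeded, bitwise-reproducible audio. They do not emulate
recorded audio: no contact mechanics, no excitation-point dependence (a real
object can sound round or spiky depending on where it is struck), no room or
microphone. A test passing on these corpora shows the pipeline implements the
model and recovers known structure under realistic noise; it does not show
that any particular human dataset will yield a given $r^2$. The published
experiments' own audio and response data are not bundled or reproduced here.

## Problem sizes in the validation suite

The recovery checks use the sizes a desk-scale replication would: boundary
recovery with 60 stimuli, score noise at 5% of the range, 20 seeds; logistic
calibration with 400 null replicates of a 30-participant experiment;
directional reproduction of the noise-band effects with 31 participants and
10 seeds. At these sizes the whole suite analyzes a few thousand half-second
stimuli, which the DFT-based filterbank keeps to minutes on one core.

## Known limitations

* The boundary scan selects $r^2$ maxima over a discrete grid; with flat
  scan profiles (all stimulus energy far below channel 20) neighboring
  boundaries are near-ties and the reported $b^\ast$ is only meaningful up to
  the tie-break rule.
* Balance depends on the intensity-normalization convention (see above);
  comparing Balance values across packages with different normalizations is
  not meaningful, though fitted predictions are.
* The Weyl synthesizer is a counting-law idealization: real membranes have
  degenerate modes, excitation-dependent amplitudes, and nonlinear contact.
* Continuity collapses the whole envelope to one ratio; stimuli with several
  dips of different depths are indistinguishable from one dip at the deepest
  point.
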