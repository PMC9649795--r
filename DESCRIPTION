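Package: roundsound
Title: Acoustic Roundness Scoring with a Balance-by-Continuity Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-parameter phenomenological model of the
    bouba-kiki effect (sound-shape correspondence): spectral Balance and
    temporal Continuity computed on a gammatone cochleagram, fitted to
    per-stimulus round/spiky judgement scores with a boundary-channel scan.
    Includes seeded synthesizers for the stimulus families used to probe
    the effect (amplitude-dipped noise bands, Weyl-law impact sounds of
    round and spiky membranes, rolling sounds and envelope-transplanted
    shaped noise) and a forced-choice respondent simulator with logistic
    regression recovery, so the full analysis loop runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
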