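Package: audithresh
Title: Adaptive Auditory Threshold Estimation with Transformed Up-Down Staircases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating auditory sensory thresholds with the
    transformed up-down (n-down/one-up) adaptive staircase family. Provides
    the staircase state machine (multiplicative step factors, reversal
    ledger, phase switching, reversal-based threshold estimates), synthesis
    of the classic psychoacoustical stimuli (pure tones, Gaussian noise,
    temporal gaps, sinusoidal amplitude modulation, WAV export), six
    ready-made forced-choice experiments (frequency, intensity and duration
    discrimination of tones, duration discrimination and gap detection of
    noise, amplitude modulation detection), simulated observers with
    parametric psychometric functions for closed-loop validation, and the
    two-file CSV session-log schema (reduced per-block thresholds and a
    complete trial-by-trial log that is sufficient to replay a session).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
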