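---
title: "Transformed up-down staircases: model, conventions, and validation"
author: "audithresh"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audithresh)
```

## The procedure

`audithresh` estimates auditory discrimination and detection thresholds
with the transformed up-down family of adaptive staircases. A
forced-choice trial presents `n_afc` intervals — `n_afc − 1` standards
and one variable at a uniformly random position — and the staircase
adapts the physical difference ("delta") between variable and standard:
after `n_down` consecutive correct responses delta is divided by the
step factor in force, after any incorrect response it is multiplied by
the same factor. Writing `p` for the probability of a correct response
at the current delta, the probability of a down step is `p^n_down`, so
the track is at equilibrium where

```
p^n_down = 1/2,  i.e.  p = 0.5^(1/n_down)
```

— 70.7 % correct for the two-down/one-up rule, 79.4 % for
three-down/one-up, 84.1 % for four-down/one-up
(`equilibrium_probability()`). Because these levels sit well above the
chance floor `1/n_afc`, the estimate is not confounded with guessing.

A *reversal* is a change in the stepping direction; a *run* is a stretch
of steps in one direction, bounded by two reversals. Thresholds are
estimated from the final reversals, either directly
(`threshold_last_k()`: mean of the last `k` reversal deltas) or through
midpoints of runs (`threshold_midpoint_runs()`: mean of the midpoints of
consecutive reversal pairs). Both support arithmetic (default) and
geometric averaging; an even number of reversals is recommended so peaks
and valleys contribute equally (the estimators warn or refuse odd
counts accordingly).

## Conventions of the state machine

Several details of an up-down implementation are conventions rather than
mathematics. The ones this package fixes, and why:

* **Initial direction is "none".** Tracks start high ("sufficiently
  high for an easy first set of trials"), so the first step — in either
  direction — records no reversal.
* **Reversal value = pre-step delta.** The delta logged at a reversal is
  the value presented on the trial that triggered the direction change,
  i.e. the extremum of the excursion, which is the stimulus value the
  reversal is classically identified with.
* **The factor in force is fixed at trial onset.** Step factors are
  organised in phases keyed to the reversal count (default: 4 reversals
  at factor 2, then 8 at √2). A reversal recorded on a trial advances
  the phase from the *next* trial on; the step on the boundary trial
  itself still uses the old factor. The alternative — applying the new
  factor to the very step that records the boundary reversal — leaves
  the track systematically high entering the fine phase: in closed-loop
  simulation it inflates the empirically tracked level by 2–3
  percentage points above the analytic equilibrium, while the
  trial-onset convention stays within about one point (the test suite
  measures both facts). Trial-onset factoring also matches what the
  per-trial log column `Factor` naturally reports.
* **Termination is immediate.** The track finishes the moment its final
  reversal is recorded; no post-terminal step is applied, so the final
  delta is the last reversal value.
* **Clamping, not rejection.** Delta is clamped to
  `[delta_min, delta_max]`; a clamped step still counts for the
  direction/grouping logic (so a track pinned at `delta_max` by a
  guessing listener can still log reversals), and clamping events are
  counted on the track.
* **Trial cap.** If `max_trials` is reached first, the threshold is
  computed on the reversals available, flagged `complete = FALSE` with a
  warning, rather than discarding the block.
* **Indices are 1-based** (intervals, targets, responses), following R
  convention, in both the API and the datafiles.

## Experiments and stimuli

Six tasks are built in; delta maps onto the manipulated parameter as

| task | delta units | variable |
|---|---|---|
| `freq_disc_tone` | Hz | standard frequency + Δ |
| `intensity_disc_tone` | dB | standard level + Δ (clamped at 0 dB FS) |
| `duration_disc_tone` / `duration_disc_noise` | ms | standard duration + Δ, ramps preserved |
| `gap_detection_noise` | ms | Δ-ms silent gap (standard has none) |
| `am_detection_noise` | % | Δ-% sinusoidal AM (standard unmodulated) |

The variable is always the "greater" stimulus; there is no roving of the
standard. Defaults mirror a short exhibition-style frequency task: a
250-ms, 1-kHz standard with 10-ms raised-cosine ramps, 3I-3AFC, starting
delta 100 Hz, one block.

Synthesis choices, where the field leaves room:

* **Levels are dB FS** — relative to digital full scale; nothing here
  calibrates absolute SPL, which depends entirely on the playback
  hardware. For tones 0 dB FS means *peak* amplitude 1.0; noise is
  scaled so its RMS equals the RMS of a full-scale sine at the same
  nominal level (1/√2 at 0 dB FS), making nominal tone and noise levels
  comparable. Default standard level is −20 dB FS, leaving headroom for
  intensity increments.
* **Sample rate defaults to 48 000 Hz** (the most common rate of
  consumer audio chains); 44 100 is equally supported. Tones at or above
  Nyquist are an error, not an aliased stimulus.
* **Noise is Gaussian and seeded**: the same `noise_spec` seed always
  regenerates the identical samples without touching the caller's RNG
  stream.
* **The gap is abrupt and centred** at the waveform midpoint (position
  is configurable); its window is simply zeroed, so output length equals
  input length.
* **AM uses a 20-Hz sinusoidal modulator** by default, zero phase, and
  divides by `1 + m` (modulation index `m`) so the output cannot clip;
  the compensation can be disabled. Depth 0 and a 0-ms gap are exact
  sample-for-sample identities.
* WAV export is 16-bit PCM mono; out-of-range samples are an error,
  never silent clipping, and a write/read round trip is exact to one
  quantisation step.

## Simulated observers

Validation is closed-loop: a parametric observer answers the trials the
staircase generates. Its probability of a correct response is

```
Psi(delta) = gamma + (1 - gamma - lambda) * F(delta)
```

with guess floor `gamma` (chance, `1/n_afc`), lapse rate `lambda`
(default 0), and `F` a logistic in log-delta (default) or a Weibull. The
log-delta axis is the natural choice here because the staircase's
multiplicative steps are additive on it. Incorrect responses choose
uniformly among the non-target intervals; interval bias is out of scope.
`alpha = Inf` (via `chance_observer()`) gives a zero-sensitivity
listener with `Psi ≡ gamma`, used for floor and clamping checks.

`tracked_performance()` replicates full tracks and evaluates the
observer's *true* `Psi` at each recovered threshold: its mean is the
performance level the rule empirically tracks.

## What the simulations show — and their known bias

With the laboratory configuration (factors 2 then √2, 4 + 8 reversals,
arithmetic mean of the last 8, logistic observer with `alpha = 10`,
`beta = 4`, `gamma = 1/3`, no lapses; 10 000 tracks in the acceptance
runs, smaller replicate counts in the unit tests), the two-down/one-up
rule tracks ≈ 71.6–71.9 % against the analytic 70.7 %, and
three-down/one-up ≈ 80.6–80.8 % against 79.4 %. The upward offset of
roughly one point is not an implementation artefact but a property of
reversal-averaged estimates at finite step size: reversal deltas
oscillate around the equilibrium on a log axis, the arithmetic mean of
that oscillation exceeds its geometric centre, and `Psi` is evaluated on
the high side. Consistently, geometric averaging lands *below* the
equilibrium, and its gap shrinks as the fine phase lengthens (the test
suite asserts the 4 → 8 → 16-reversal trend); the arithmetic default's
bias instead saturates toward its stationary value as tracks lengthen,
so more reversals do not remove it. The short 6-reversal configuration
(2 at factor 2, 4 at √2, threshold on the last 4) is close to unbiased
— across observer thresholds of 5, 10 and 20 delta units it tracks
70.5–71.7 %, within two points of 70.7 % — because the descent
transient partially cancels the stationary bias; this motivates its use
where testing time is scarce.

What passing these simulations does *not* show about real data: the
observer is stationary (no drift in attention or criterion), lapse-free
by default, bias-free across intervals, and answers every trial; real
listeners are none of these, and absolute levels depend on uncontrolled
hardware. The simulations validate the *procedure*, not human
performance.

## Datafiles and replay

Each session writes two CSV files. The *reduced* file holds the
participant details and one threshold row per block. The *extended* file
is one row per trial and additionally carries the experiment name,
standard-stimulus characteristics and the full staircase settings
(`nAFC`, `ISI`, `ITI`, `Reversal threshold`, `Algorithm`, phase
factors, bounds, seed) on every row, plus the per-trial `Factor`,
`Delta`, `Target`, `Response`, `Correct`, `Reversals` and a nominal
`Time` column. Timing in simulation is nominal — trial onsets computed
from stimulus duration, ISI and ITI; nothing sleeps — so logs are
deterministic. Numeric fields are written with the shortest decimal
representation that parses back to the identical double, which is what
makes `replay_session()` exact: it rebuilds the session from the log's
metadata and the recorded correct/incorrect sequence alone, and
rewriting the replayed session reproduces the original file byte for
byte. The extended log is, in that precise sense, a sufficient statistic
for the session.

## Problem sizes and tolerances

The acceptance computations use 10 000 replicate tracks per rule and
10 000 trials per chance floor, sizes at which the Monte-Carlo standard
error of a tracked percentage is about 0.1 points and of a floor about
0.5 points. Unit tests use 150–2500 replicates with correspondingly
wider assertions. Equilibrium probabilities are checked to 1 × 10⁻¹²;
staircase trajectories are cross-checked exactly (to floating-point
identity) against an independent brute-force enumerator over random
response strings.

## Limitations

* Only multiplicative (factor) stepping is implemented — no additive
  staircases, and no parametric adaptive procedures (PEST, QUEST,
  maximum-likelihood), which serve different designs.
* No psychometric-function fitting on the trial logs; the extended CSV
  is designed so external tools can do that on all trials.
* No absolute calibration, headphone screening, or real-time playback;
  stimuli are rendered to WAV for inspection or external presentation.
* Whether a clamped step at `delta_max` should count as a direction
  change is genuinely ambiguous in the field; this package counts it
  (and logs the clamp), which matters only for zero-sensitivity
  listeners pinned at the bounds.
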