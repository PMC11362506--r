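# audithresh

Adaptive estimation of auditory sensory thresholds with transformed
up-down (n-down/one-up) staircases, in R.

`audithresh` is for hearing researchers, psychophysics teachers and
students who want to run, simulate or study the classic adaptive
threshold-tracking procedures without a lab stack: it implements the
staircase state machine, the six classic forced-choice experiments it
drives (frequency, intensity and duration discrimination of pure tones;
duration discrimination and gap detection of noise; amplitude-modulation
detection with a noise carrier), digital stimulus synthesis with WAV
export, simulated listeners for closed-loop validation, and a two-file
CSV session log that is a sufficient statistic for replaying every
session.

## The method

A trial presents *n* intervals: *n* − 1 copies of a **standard** stimulus
and one **variable** at a uniformly random position, differing only in
the manipulated parameter by the current **delta** (Δf Hz, ΔL dB, Δt ms,
gap ms, or AM depth %). The listener names the odd interval. The
**n-down/one-up rule** divides delta by a step factor after *n*
consecutive correct responses and multiplies it by the same factor after
any error. At equilibrium the probability of a down step equals that of
an up step,

    p^n = 1/2   ⟹   p = 0.5^(1/n),

so the two-down/one-up rule converges on the stimulus difference
yielding 70.7 % correct, three-down/one-up on 79.4 %, and a hypothetical
four-down/one-up on 84.1 % — all above the chance floor 1/n of the
forced-choice task, which is what makes the rules attractive with
guessing listeners. A change of stepping direction is a **reversal**;
step factors are organised in phases keyed to the reversal count (large
factor, e.g. 2, to approach threshold quickly; then a small one, e.g.
√2, for fine tracking), and the threshold is the arithmetic (or
geometric) mean of the deltas logged at the final, small-factor
reversals — an even number of them, to balance peaks and valleys.

## Worked example

A short exhibition-style frequency-discrimination session — 3I-3AFC,
two-down/one-up, 2 reversals at factor 2 then 4 at √2, threshold on the
last four reversals — driven by a simulated listener whose true
threshold is 10 Hz:

```r
library(audithresh)

spec <- experiment_spec("freq_disc_tone")          # 250-ms, 1-kHz standard
cfg  <- staircase_config(2, phases = list(c(2, 2), c(4, sqrt(2))),
                         start_delta = 100, reversal_threshold_k = 4)
obs  <- psychometric_observer(alpha = 10, beta = 4, gamma = 1/3)

session <- run_session(spec, cfg, observer_responder(obs),
                       n_blocks = 3, seed = 2023, out_dir = "demo")
session
#> freq_disc_tone session: 3 block(s), threshold 12.05 Hz
#>   block thresholds: 10.4, 12.5, 13.26
```

The session threshold (12.05 Hz) is the mean of the three block
thresholds, each the mean of that block's last four reversal deltas; the
two datafiles land in `demo/`. How well does this short staircase do its
job? Replicating the closed loop 2000 times and evaluating the
observer's true psychometric function at every recovered threshold:

```r
tracked_performance(cfg, spec, obs, n_replicates = 2000, seed = 1)
#> tracked performance over 2000 tracks:
#>   mean threshold 11.03 (SD 2.588)
#>   mean Psi(threshold) 0.707 (SD 0.133); analytic equilibrium 0.707
```

The rule empirically tracks the 70.7 % point it is supposed to track,
and the mean recovered threshold (11.0 Hz) sits near the observer's
10-Hz 70.7 %-correct point.

A command-line front end is installed as `exec/audithresh`
(subcommands `run`, `simulate`, `convergence`, `make-stimuli`); see
`inst/extdata/freq_disc_example.yaml` for the configuration format.

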