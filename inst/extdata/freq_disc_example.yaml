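# Frequency discrimination of a 1-kHz pure tone: 3I-3AFC, two-down/one-up,
# short exhibition-style staircase (6 reversals, threshold on the last 4).
experiment:
  experiment: freq_disc_tone
  standard:
    frequencyHz: 1000
    durationMs: 250
    levelDbfs: -20
    rampMs: 10
  nAfc: 3
  isiMs: 500
  itiMs: 500
  nBlocks: 1
  feedback: true
  startDelta: 100
staircase:
  rule: 2d1u
  phases:
    - [2, 2.0]
    - [4, 1.4142135623730951]
  reversalThreshold: 4
  meanType: arithmetic
  maxTrials: 1000
observer:
  model: logistic
  alphaDelta: 10
  beta: 4
  gammaAuto: true
  lambda: 0
  seed: 1
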