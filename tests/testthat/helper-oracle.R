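# Independent brute-force staircase enumerator used to cross-check the
# package's state machine. Deliberately structured differently from
# update_track(): a first pass derives the up/down step events from the
# response string, a second pass folds the events into a delta trajectory
# and reversal ledger.
oracle_staircase <- function(responses, n_down, phase_counts, phase_factors,
                             start_delta, delta_min = start_delta / 1e4,
                             delta_max = start_delta * 1e2,
                             max_trials = 1000L) {
  # pass 1: step events (trial index, direction +1 up / -1 down)
  ev_trial <- integer(0); ev_dir <- integer(0)
  streak <- 0L
  for (i in seq_along(responses)) {
    if (i > max_trials) break
    if (responses[i]) {
      streak <- streak + 1L
      if (streak == n_down) {
        ev_trial <- c(ev_trial, i); ev_dir <- c(ev_dir, -1L)
        streak <- 0L
      }
    } else {
      ev_trial <- c(ev_trial, i); ev_dir <- c(ev_dir, 1L)
      streak <- 0L
    }
  }
  # pass 2: fold events into the trajectory
  bounds <- cumsum(phase_counts)
  total <- sum(phase_counts)
  delta <- start_delta
  prev_dir <- 0L
  rev_trial <- integer(0); rev_delta <- numeric(0)
  stopped_at <- NA_integer_
  for (j in seq_along(ev_trial)) {
    dir <- ev_dir[j]
    # factor in force at this trial: phase of the next reversal to collect
    fac <- phase_factors[which(length(rev_delta) + 1L <= bounds)[1]]
    if (prev_dir != 0L && dir != prev_dir) {
      rev_trial <- c(rev_trial, ev_trial[j])
      rev_delta <- c(rev_delta, delta)
    }
    if (length(rev_delta) >= total) {  # final reversal: no further step
      prev_dir <- dir
      stopped_at <- ev_trial[j]
      break
    }
    delta <- if (dir < 0L) delta / fac else delta * fac
    delta <- min(max(delta, delta_min), delta_max)
    prev_dir <- dir
  }
  n_trials <- if (!is.na(stopped_at)) stopped_at
              else min(length(responses), max_trials)
  list(reversal_trial = rev_trial, reversal_delta = rev_delta,
       final_delta = delta, n_trials = n_trials,
       finished = !is.na(stopped_at) || n_trials >= max_trials)
}

# Drive the package engine with a response string, stopping when the track
# finishes; returns the final state.
drive_track <- function(responses, config) {
  state <- new_track(config)
  for (r in responses) {
    if (state$finished) break
    state <- update_track(state, config, r)
  }
  state
}
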