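# Sessions, blocks, familiarisation, and the two CSV datafiles.
#
# A session runs n_blocks staircase blocks of one experiment and reports
# the mean of the block thresholds. Two datafiles are produced: a reduced
# file (demographics + one threshold row per block) and an extended file
# (one row per trial, carrying the full experiment and staircase settings
# so that the log is a sufficient statistic for replaying the block).
#
# In simulation mode nothing sleeps: the Time column holds the nominal
# trial onset (ms from block start) computed from the stimulus duration,
# ISI and ITI, so logs are deterministic and replayable.

#' Participant details
#'
#' All fields are optional: anonymous deployments may leave demographics
#' empty, and missing fields are written as empty CSV cells.
#'
#' @param name,surname,biological_sex,notes Optional strings.
#' @param age Optional integer.
#' @return An object of class `participant_info`.
#' @export
participant_info <- function(name = "", surname = "", age = NA_integer_,
                             biological_sex = "", notes = "") {
  structure(list(name = as.character(name), surname = as.character(surname),
                 age = as.integer(age),
                 biological_sex = as.character(biological_sex),
                 notes = as.character(notes)),
            class = "participant_info")
}

#' Responder replaying a fixed list of interval choices
#'
#' @param responses Integer vector of 1-based interval choices, consumed
#'   one per trial. Running out of responses is an error.
#' @return A function `trial -> response index` for [run_block()] /
#'   [run_session()].
#' @export
scripted_responder <- function(responses) {
  responses <- as.integer(responses)
  i <- 0L
  function(trial) {
    i <<- i + 1L
    if (i > length(responses)) stop("scripted responder ran out of responses")
    responses[i]
  }
}

#' Responder replaying a correct/incorrect pattern
#'
#' Answers the target interval when the next scripted value is TRUE and
#' a fixed wrong interval otherwise. Useful for hand-traced staircase
#' tests and for replaying logged blocks.
#'
#' @param correct Logical vector, one entry per trial.
#' @return A function `trial -> response index`.
#' @export
correctness_responder <- function(correct) {
  correct <- as.logical(correct)
  i <- 0L
  function(trial) {
    i <<- i + 1L
    if (i > length(correct)) stop("correctness responder ran out of responses")
    if (correct[i]) trial$target_index
    else seq_len(trial$n_afc)[-trial$target_index][1L]
  }
}

nominal_trial_ms <- function(spec) {
  spec$n_afc * spec$standard$duration_ms +
    (spec$n_afc - 1) * spec$isi_ms + spec$iti_ms
}

#' Run the familiarisation phase
#'
#' Presents easy trials at fixed deltas until the responder produces
#' `required_streak` consecutive correct responses (pass) or the trial
#' cap is reached (fail). An error resets the streak. The default deltas
#' are the experiment's starting delta and half of it — for the default
#' frequency task, 100 and 50 Hz.
#'
#' @param spec An [experiment_spec()].
#' @param responder A responder function (`trial -> response index`).
#' @param fixed_deltas Deltas sampled (uniformly) for the easy trials.
#' @param required_streak Consecutive correct responses needed to pass.
#' @param max_trials Trial cap before the familiarisation fails.
#' @return A list: `passed`, `n_trials`, and a per-trial `log`
#'   data frame (`trial`, `delta`, `target`, `response`, `correct`).
#' @export
run_familiarisation <- function(spec, responder, fixed_deltas = NULL,
                                required_streak = 6L, max_trials = 30L) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(fixed_deltas))
    fixed_deltas <- c(spec$start_delta, spec$start_delta / 2)
  required_streak <- as.integer(required_streak)
  if (required_streak < 1L) stop("'required_streak' must be at least 1")
  streak <- 0L
  log <- list(trial = integer(0), delta = numeric(0), target = integer(0),
              response = integer(0), correct = logical(0))
  n <- 0L
  while (streak < required_streak && n < max_trials) {
    n <- n + 1L
    d <- fixed_deltas[sample.int(length(fixed_deltas), 1L)]
    tr <- make_trial(spec, d)
    resp <- responder(tr)
    ok <- score_response(tr, resp, feedback = FALSE)
    streak <- if (ok) streak + 1L else 0L
    log$trial[n] <- n; log$delta[n] <- d; log$target[n] <- tr$target_index
    log$response[n] <- as.integer(resp); log$correct[n] <- ok
  }
  list(passed = streak >= required_streak, n_trials = n,
       log = as.data.frame(log))
}

#' Run one staircase block
#'
#' The closed loop: assemble a trial at the track's current delta, obtain
#' a response, score it, update the track; repeat until the track
#' finishes. The block threshold is the configured reversal-based
#' estimate.
#'
#' @param spec An [experiment_spec()].
#' @param config A [staircase_config()].
#' @param responder A responder function (`trial -> response index`),
#'   e.g. [observer_responder()] or [scripted_responder()].
#' @param block_index Block number recorded in the trial log.
#' @param synthesize Render waveforms for every trial (slow; only needed
#'   for playback).
#' @param record Build the per-trial log (switch off for bulk
#'   simulation).
#' @return A list with `result` (block index, `threshold` estimate,
#'   `reversal_deltas`, `n_trials`, `complete`) and `records` (a
#'   data frame, `NULL` when `record = FALSE`).
#' @export
run_block <- function(spec, config, responder, block_index = 1L,
                      synthesize = FALSE, record = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"),
            inherits(config, "staircase_config"))
  state <- new_track(config)
  cap <- config$max_trials
  if (record) {
    rec_factor <- numeric(cap); rec_delta <- numeric(cap)
    rec_target <- integer(cap); rec_response <- integer(cap)
    rec_correct <- logical(cap); rec_revs <- integer(cap)
  }
  i <- 0L
  while (!state$finished) {
    i <- i + 1L
    fac <- current_factor(state, config)
    delta <- state$delta
    tr <- make_trial(spec, delta, synthesize = synthesize)
    resp <- responder(tr)
    ok <- score_response(tr, resp, feedback = FALSE)
    state <- update_track(state, config, ok)
    if (record) {
      rec_factor[i] <- fac; rec_delta[i] <- delta
      rec_target[i] <- tr$target_index; rec_response[i] <- as.integer(resp)
      rec_correct[i] <- ok; rec_revs[i] <- length(state$reversal_delta)
    }
  }
  est <- track_threshold(state, config)
  result <- list(block_index = as.integer(block_index), threshold = est,
                 reversal_deltas = state$reversal_delta,
                 reversal_trials = state$reversal_trial,
                 n_trials = state$trial_count, complete = est$complete)
  records <- NULL
  if (record) {
    idx <- seq_len(i)
    records <- data.frame(
      Block = as.integer(block_index), Trial = idx,
      Factor = rec_factor[idx], Delta = rec_delta[idx],
      Target = rec_target[idx], Response = rec_response[idx],
      Correct = as.integer(rec_correct[idx]), Reversals = rec_revs[idx],
      Time = (idx - 1L) * nominal_trial_ms(spec))
  }
  list(result = result, records = records)
}

#' Run a complete session
#'
#' Runs `n_blocks` staircase blocks and reports the session threshold:
#' the arithmetic mean of the block thresholds. Incomplete blocks (trial
#' cap hit) are flagged; the session mean is computed over the completed
#' blocks, with a warning, unless none completed.
#'
#' @param spec An [experiment_spec()].
#' @param config A [staircase_config()].
#' @param responder A responder function.
#' @param n_blocks Number of blocks (default from `spec`).
#' @param participant A [participant_info()].
#' @param seed Optional seed applied once before the first block; stored
#'   in the extended log.
#' @param out_dir If given, the reduced and extended CSV files are
#'   written there as `<basename>_reduced.csv` /
#'   `<basename>_extended.csv`.
#' @param basename File name stem for the datafiles.
#' @return An object of class `session`: specs, participant, per-block
#'   results, the trial `records` data frame, and `threshold`.
#' @export
run_session <- function(spec, config, responder, n_blocks = spec$n_blocks,
                        participant = participant_info(), seed = NULL,
                        out_dir = NULL, basename = "session") {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("'n_blocks' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  blocks <- vector("list", n_blocks)
  recs <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    blk <- run_block(spec, config, responder, block_index = b)
    blocks[[b]] <- blk$result
    recs[[b]] <- blk$records
  }
  thr <- vapply(blocks, function(b) b$threshold$value, numeric(1))
  ok <- vapply(blocks, function(b) isTRUE(b$complete), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " block(s) incomplete; session threshold computed ",
            "over the ", if (any(ok)) "completed" else "available",
            " blocks", call. = FALSE)
  }
  use <- if (any(ok)) thr[ok] else thr[!is.na(thr)]
  session <- structure(list(
    spec = spec, config = config, participant = participant,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    blocks = blocks, records = do.call(rbind, recs),
    block_thresholds = thr, threshold = mean(use)
  ), class = "session")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_reduced_csv(session, file.path(out_dir, paste0(basename, "_reduced.csv")))
    write_extended_csv(session, file.path(out_dir, paste0(basename, "_extended.csv")))
  }
  session
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("%s session: %d block(s), threshold %.4g %s\n", x$spec$name,
              length(x$blocks), x$threshold, x$spec$delta_units))
  cat(sprintf("  block thresholds: %s\n",
              paste(sprintf("%.4g", x$block_thresholds), collapse = ", ")))
  invisible(x)
}

# Shortest decimal string that parses back to exactly the same double.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

csv_quote <- function(x) {
  x[is.na(x)] <- ""
  paste0("\"", gsub("\"", "\"\"", x), "\"")
}

write_csv_matrix <- function(cols, path) {
  header <- paste(csv_quote(names(cols)), collapse = ",")
  body <- do.call(paste, c(unname(cols), sep = ","))
  con <- file(path, "wb")  # binary: fixed "\n" endings on every platform
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

std_field <- function(std, field) if (is.null(std[[field]])) NA_real_ else std[[field]]

#' Write the reduced datafile
#'
#' Demographics plus one threshold row per block.
#'
#' @param session A [run_session()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reduced_csv <- function(session, path) {
  stopifnot(inherits(session, "session"))
  p <- session$participant
  nb <- length(session$blocks)
  cols <- list(
    Name = rep(csv_quote(p$name), nb),
    Surname = rep(csv_quote(p$surname), nb),
    Age = rep(if (is.na(p$age)) "" else as.character(p$age), nb),
    BiologicalSex = rep(csv_quote(p$biological_sex), nb),
    Notes = rep(csv_quote(p$notes), nb),
    Experiment = rep(csv_quote(session$spec$name), nb),
    Block = as.character(seq_len(nb)),
    Threshold = fmt_num(session$block_thresholds),
    Complete = as.character(as.integer(vapply(session$blocks,
                                              function(b) b$complete, logical(1))))
  )
  write_csv_matrix(cols, path)
}

extended_columns <- c("Name", "Surname", "Age", "BiologicalSex", "Notes",
                      "Experiment", "Frequency", "Duration", "Level", "Ramps",
                      "SampleRate", "NoiseSeed", "nAFC", "ISI", "ITI",
                      "Reversal threshold", "Algorithm", "Phases", "MeanType",
                      "StartDelta", "DeltaMin", "DeltaMax", "MaxTrials",
                      "SessionSeed", "Block", "Trial", "Factor", "Delta",
                      "Target", "Response", "Correct", "Reversals", "Time")

encode_phases <- function(config)
  paste(sprintf("%dx%s", config$phase_counts, fmt_num(config$phase_factors)),
        collapse = ";")

decode_phases <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(p, "x", fixed = TRUE)[[1]]
    c(as.numeric(kv[1]), as.numeric(kv[2]))
  })
}

#' Write the extended (complete) datafile
#'
#' One row per trial. Alongside the trial-by-trial columns (Delta,
#' Correct, Reversals, ...) each row carries the participant details,
#' the standard-stimulus characteristics and the full staircase settings
#' (nAFC, ISI, ITI, Reversal threshold, Algorithm, phase factors), so
#' the file alone suffices to replay the session (see
#' [replay_session()]). Numeric values are written with enough digits to
#' parse back to the identical double.
#'
#' @param session A [run_session()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_extended_csv <- function(session, path) {
  stopifnot(inherits(session, "session"))
  p <- session$participant; sp <- session$spec; cfg <- session$config
  r <- session$records
  n <- nrow(r)
  std <- sp$standard
  const <- list(
    Name = csv_quote(p$name), Surname = csv_quote(p$surname),
    Age = if (is.na(p$age)) "" else as.character(p$age),
    BiologicalSex = csv_quote(p$biological_sex), Notes = csv_quote(p$notes),
    Experiment = csv_quote(sp$name),
    Frequency = fmt_num(std_field(std, "frequency")),
    Duration = fmt_num(std$duration_ms),
    Level = fmt_num(std$level_dbfs),
    Ramps = fmt_num(std$ramp_ms),
    SampleRate = fmt_num(sp$sample_rate),
    NoiseSeed = if (is.null(std$seed)) "" else as.character(std$seed),
    nAFC = as.character(sp$n_afc),
    ISI = fmt_num(sp$isi_ms), ITI = fmt_num(sp$iti_ms),
    `Reversal threshold` = as.character(cfg$reversal_threshold_k),
    Algorithm = csv_quote(sprintf("%d-down/1-up", cfg$n_down)),
    Phases = csv_quote(encode_phases(cfg)),
    MeanType = csv_quote(cfg$mean_type),
    StartDelta = fmt_num(cfg$start_delta),
    DeltaMin = fmt_num(cfg$delta_min), DeltaMax = fmt_num(cfg$delta_max),
    MaxTrials = as.character(cfg$max_trials),
    SessionSeed = if (is.na(session$seed)) "" else as.character(session$seed)
  )
  cols <- c(lapply(const, rep, n), list(
    Block = as.character(r$Block), Trial = as.character(r$Trial),
    Factor = fmt_num(r$Factor), Delta = fmt_num(r$Delta),
    Target = as.character(r$Target), Response = as.character(r$Response),
    Correct = as.character(r$Correct), Reversals = as.character(r$Reversals),
    Time = fmt_num(r$Time)))
  stopifnot(identical(names(cols), extended_columns))
  write_csv_matrix(cols, path)
}

#' Read an extended datafile
#'
#' @param path CSV path written by [write_extended_csv()].
#' @return A data frame with the original column names (including
#'   `"Reversal threshold"`).
#' @export
read_extended_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

session_from_log <- function(df) {
  std_is_tone <- !is.na(df$Frequency[1]) && df$Frequency[1] != ""
  std <- if (std_is_tone) {
    tone_spec(as.numeric(df$Frequency[1]), as.numeric(df$Duration[1]),
              as.numeric(df$Level[1]), as.numeric(df$Ramps[1]))
  } else {
    noise_spec(as.numeric(df$Duration[1]), as.numeric(df$Level[1]),
               as.numeric(df$Ramps[1]), as.integer(df$NoiseSeed[1]))
  }
  spec <- experiment_spec(df$Experiment[1], standard = std,
                          start_delta = as.numeric(df$StartDelta[1]),
                          n_afc = as.integer(df$nAFC[1]),
                          isi_ms = as.numeric(df$ISI[1]),
                          iti_ms = as.numeric(df$ITI[1]),
                          n_blocks = max(as.integer(df$Block)),
                          sample_rate = as.numeric(df$SampleRate[1]))
  n_down <- as.integer(sub("-down/1-up", "", df$Algorithm[1], fixed = TRUE))
  config <- suppressWarnings(staircase_config(
    n_down = n_down, phases = decode_phases(df$Phases[1]),
    start_delta = as.numeric(df$StartDelta[1]),
    reversal_threshold_k = as.integer(df[["Reversal threshold"]][1]),
    mean_type = df$MeanType[1],
    delta_min = as.numeric(df$DeltaMin[1]),
    delta_max = as.numeric(df$DeltaMax[1]),
    max_trials = as.integer(df$MaxTrials[1])))
  participant <- participant_info(df$Name[1], df$Surname[1],
                                  if (is.na(df$Age[1]) || df$Age[1] == "") NA
                                  else as.integer(df$Age[1]),
                                  df$BiologicalSex[1], df$Notes[1])
  list(spec = spec, config = config, participant = participant)
}

#' Replay an extended datafile through the staircase engine
#'
#' Reconstructs the experiment and staircase settings from the log's
#' metadata columns, then re-runs every block by feeding the logged
#' correct/incorrect sequence through the state machine, with the logged
#' target and response indices. Because the extended file is a sufficient
#' statistic for the session, the regenerated session reproduces the
#' original trial stream — writing it back out with
#' [write_extended_csv()] gives a byte-identical file.
#'
#' @param path Path to an extended CSV, or the data frame from
#'   [read_extended_csv()].
#' @return A `session` object rebuilt from the log.
#' @export
replay_session <- function(path) {
  df <- if (is.data.frame(path)) path else read_extended_csv(path)
  meta <- session_from_log(df)
  spec <- meta$spec; config <- meta$config
  blocks <- list(); recs <- list()
  for (b in sort(unique(df$Block))) {
    rows <- df[df$Block == b, ]
    state <- new_track(config)
    n <- nrow(rows)
    fac <- numeric(n); dlt <- numeric(n); revs <- integer(n)
    for (i in seq_len(n)) {
      fac[i] <- current_factor(state, config)
      dlt[i] <- state$delta
      state <- update_track(state, config, as.logical(rows$Correct[i]))
      revs[i] <- length(state$reversal_delta)
    }
    if (!state$finished)
      stop("log for block ", b, " ends before the staircase terminates")
    est <- track_threshold(state, config)
    blocks[[length(blocks) + 1L]] <- list(
      block_index = as.integer(b), threshold = est,
      reversal_deltas = state$reversal_delta,
      reversal_trials = state$reversal_trial,
      n_trials = state$trial_count, complete = est$complete)
    recs[[length(recs) + 1L]] <- data.frame(
      Block = as.integer(b), Trial = seq_len(n), Factor = fac, Delta = dlt,
      Target = as.integer(rows$Target), Response = as.integer(rows$Response),
      Correct = as.integer(rows$Target == rows$Response), Reversals = revs,
      Time = (seq_len(n) - 1L) * nominal_trial_ms(spec))
  }
  thr <- vapply(blocks, function(x) x$threshold$value, numeric(1))
  ok <- vapply(blocks, function(x) isTRUE(x$complete), logical(1))
  structure(list(
    spec = spec, config = config, participant = meta$participant,
    seed = if (df$SessionSeed[1] %in% c("", NA)) NA_integer_
           else as.integer(df$SessionSeed[1]),
    blocks = blocks, records = do.call(rbind, recs),
    block_thresholds = thr,
    threshold = mean(if (any(ok)) thr[ok] else thr)
  ), class = "session")
}
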