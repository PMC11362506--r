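# The six built-in forced-choice experiments.
#
# Every experiment presents n_afc intervals per trial: n_afc - 1 copies of
# the standard stimulus and one variable stimulus at a uniformly random
# position. The variable is identical to the standard except for the one
# manipulated parameter, offset by the staircase's current delta. The
# variable is always the "greater" stimulus: higher frequency, higher
# level, longer duration, gap present, modulation present.

EXPERIMENT_NAMES <- c("freq_disc_tone", "intensity_disc_tone",
                      "duration_disc_tone", "duration_disc_noise",
                      "gap_detection_noise", "am_detection_noise")

DELTA_UNITS <- c(freq_disc_tone = "Hz", intensity_disc_tone = "dB",
                 duration_disc_tone = "ms", duration_disc_noise = "ms",
                 gap_detection_noise = "ms", am_detection_noise = "percent")

#' Define a forced-choice auditory experiment
#'
#' Six classic tasks are built in: frequency, intensity and duration
#' discrimination of pure tones; duration discrimination and gap
#' detection with noise; amplitude modulation detection with a noise
#' carrier. Defaults mirror a short exhibition-style frequency task: a
#' 250-ms, 1-kHz standard with 10-ms raised-cosine ramps, 3I-3AFC, one
#' block, starting delta 100 Hz.
#'
#' @param name One of `"freq_disc_tone"`, `"intensity_disc_tone"`,
#'   `"duration_disc_tone"`, `"duration_disc_noise"`,
#'   `"gap_detection_noise"`, `"am_detection_noise"`.
#' @param standard A [tone_spec()] or [noise_spec()] describing the
#'   standard stimulus; a task-appropriate default is supplied.
#' @param start_delta Delta for the first trial, in the task's units
#'   (Hz, dB, ms or percent of modulation depth).
#' @param delta_bounds Length-2 numeric, the allowed delta range.
#' @param n_afc Number of intervals/alternatives (>= 2; built-ins use 2
#'   or 3, intervals = alternatives).
#' @param isi_ms Inter-stimulus interval: silence between the intervals
#'   of one trial, ms.
#' @param iti_ms Inter-trial interval, ms.
#' @param n_blocks Number of blocks of trials in a session.
#' @param feedback Whether trial-by-trial feedback is given.
#' @param sample_rate Synthesis sample rate, samples/s.
#' @param am_mod_rate_hz Modulation rate for the AM task, Hz.
#' @param gap_position Gap placement for the gap task (see [insert_gap()]).
#' @return An object of class `experiment_spec`.
#' @examples
#' experiment_spec("freq_disc_tone")
#' @export
experiment_spec <- function(name = EXPERIMENT_NAMES,
                            standard = NULL,
                            start_delta = NULL,
                            delta_bounds = NULL,
                            n_afc = 3L,
                            isi_ms = 500,
                            iti_ms = 500,
                            n_blocks = 1L,
                            feedback = TRUE,
                            sample_rate = 48000,
                            am_mod_rate_hz = 20,
                            gap_position = "center") {
  name <- match.arg(name)
  if (is.null(standard)) standard <- default_standard(name)
  tone_task <- name %in% c("freq_disc_tone", "intensity_disc_tone",
                           "duration_disc_tone")
  if (tone_task && !inherits(standard, "tone_spec"))
    stop("'", name, "' needs a tone_spec standard")
  if (!tone_task && !inherits(standard, "noise_spec"))
    stop("'", name, "' needs a noise_spec standard")
  if (is.null(start_delta))
    start_delta <- switch(name,
      freq_disc_tone = 100, intensity_disc_tone = 10,
      duration_disc_tone = 100, duration_disc_noise = 100,
      gap_detection_noise = 20, am_detection_noise = 100)
  if (is.null(delta_bounds))
    delta_bounds <- switch(name,
      freq_disc_tone = c(1e-2, 4000),
      intensity_disc_tone = c(1e-3, 60),
      duration_disc_tone = c(1e-2, 1000),
      duration_disc_noise = c(1e-2, 1000),
      gap_detection_noise = c(1e-2, 0.8 * standard$duration_ms),
      am_detection_noise = c(1e-2, 100))
  if (length(delta_bounds) != 2L || delta_bounds[1] <= 0 ||
      delta_bounds[1] >= delta_bounds[2])
    stop("'delta_bounds' must be two increasing positive numbers")
  if (name == "gap_detection_noise" && delta_bounds[2] >= standard$duration_ms)
    stop("gap delta_max must be shorter than the standard duration")
  if (name == "am_detection_noise" && delta_bounds[2] > 100)
    stop("modulation depth cannot exceed 100 percent")
  n_afc <- as.integer(n_afc)
  if (n_afc < 2L) stop("'n_afc' must be at least 2")
  if (isi_ms < 0 || iti_ms < 0) stop("ISI and ITI must be non-negative")
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("'n_blocks' must be at least 1")
  structure(list(
    name = name, standard = standard,
    delta_units = unname(DELTA_UNITS[name]),
    start_delta = as.numeric(start_delta),
    delta_bounds = as.numeric(delta_bounds),
    n_afc = n_afc, isi_ms = as.numeric(isi_ms), iti_ms = as.numeric(iti_ms),
    n_blocks = n_blocks, feedback = isTRUE(feedback),
    sample_rate = as.numeric(sample_rate),
    am_mod_rate_hz = as.numeric(am_mod_rate_hz),
    gap_position = gap_position
  ), class = "experiment_spec")
}

default_standard <- function(name) {
  switch(name,
    freq_disc_tone = ,
    intensity_disc_tone = ,
    duration_disc_tone = tone_spec(1000, 250, -20, 10),
    duration_disc_noise = noise_spec(250, -20, 10),
    gap_detection_noise = ,
    am_detection_noise = noise_spec(500, -20, 10))
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("%s: %dI-%dAFC, delta in %s starting at %.4g, ISI %g ms, ITI %g ms, %d block(s)\n",
              x$name, x$n_afc, x$n_afc, x$delta_units, x$start_delta,
              x$isi_ms, x$iti_ms, x$n_blocks))
  invisible(x)
}

#' Parameters of the variable stimulus at a given delta
#'
#' Maps the staircase's delta onto the physical parameter the experiment
#' manipulates: frequency (standard + delta Hz), level (standard + delta
#' dB, clamped at 0 dB FS with a warning), duration (standard + delta ms,
#' ramps preserved), gap duration (delta ms of silence; the standard has
#' none) or modulation depth (delta percent; the standard is
#' unmodulated). All other parameters are copied from the standard.
#'
#' @param spec An `experiment_spec`.
#' @param delta Positive delta within `spec$delta_bounds`.
#' @return A list with the standard's class plus, for the gap and AM
#'   tasks, the extra `gap_ms` / `depth_percent` field.
#' @examples
#' sp <- experiment_spec("freq_disc_tone")
#' variable_from_delta(sp, 200)$frequency  # 1200
#' @export
variable_from_delta <- function(spec, delta) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (delta < spec$delta_bounds[1] || delta > spec$delta_bounds[2])
    stop("delta ", delta, " outside bounds [", spec$delta_bounds[1], ", ",
         spec$delta_bounds[2], "]")
  v <- spec$standard
  switch(spec$name,
    freq_disc_tone = { v$frequency <- v$frequency + delta },
    intensity_disc_tone = {
      lv <- v$level_dbfs + delta
      if (lv > 0) {
        warning("variable level clamped at 0 dB FS (digital full scale)",
                call. = FALSE)
        lv <- 0
      }
      v$level_dbfs <- lv
    },
    duration_disc_tone = ,
    duration_disc_noise = { v$duration_ms <- v$duration_ms + delta },
    gap_detection_noise = { v$gap_ms <- delta },
    am_detection_noise = { v$depth_percent <- delta })
  v
}

synth_stimulus <- function(spec, params) {
  if (inherits(params, "tone_spec")) {
    pure_tone(params, spec$sample_rate)
  } else {
    w <- white_noise(params, spec$sample_rate)
    if (!is.null(params$gap_ms))
      w <- insert_gap(w, params$gap_ms, spec$gap_position)
    if (!is.null(params$depth_percent))
      w <- amplitude_modulate(w, params$depth_percent, spec$am_mod_rate_hz)
    w
  }
}

#' Assemble one forced-choice trial
#'
#' Builds `n_afc` intervals — `n_afc - 1` standards and one variable at a
#' uniformly random position — separated by the ISI. The target position
#' is drawn from the caller's RNG stream, so a fixed seed gives a fixed
#' trial sequence. By default only the stimulus parameters are stored;
#' `synthesize = TRUE` additionally renders the interval waveforms.
#'
#' @param spec An `experiment_spec`.
#' @param delta Current staircase delta, within bounds.
#' @param synthesize Render interval waveforms (needed for playback or
#'   export, not for simulation).
#' @return An object of class `trial`: interval parameter list, optional
#'   `interval_waveforms`, 1-based `target_index`, `delta`, `isi_ms`.
#' @export
make_trial <- function(spec, delta, synthesize = FALSE) {
  variable <- variable_from_delta(spec, delta)
  target <- sample.int(spec$n_afc, 1L)
  params <- rep(list(spec$standard), spec$n_afc)
  params[[target]] <- variable
  tr <- list(interval_params = params, target_index = target,
             delta = delta, n_afc = spec$n_afc, isi_ms = spec$isi_ms)
  if (synthesize)
    tr$interval_waveforms <- lapply(params, function(p) synth_stimulus(spec, p))
  class(tr) <- "trial"
  tr
}

#' Score a forced-choice response
#'
#' @param trial A [make_trial()] result.
#' @param response_index 1-based chosen interval.
#' @param feedback Emit a feedback message.
#' @return `TRUE` iff the response names the target interval.
#' @export
score_response <- function(trial, response_index, feedback = FALSE) {
  stopifnot(inherits(trial, "trial"))
  response_index <- as.integer(response_index)
  if (is.na(response_index) || response_index < 1L ||
      response_index > trial$n_afc)
    stop("response index must be in 1..", trial$n_afc)
  correct <- response_index == trial$target_index
  if (feedback)
    message(if (correct) "Correct!" else "Wrong.")
  correct
}
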