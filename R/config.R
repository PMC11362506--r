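# YAML/JSON run configuration.
#
# One file may hold three sections:
#   experiment: experiment, standard {frequencyHz, durationMs, levelDbfs,
#               rampMs}, nAfc, isiMs, itiMs, nBlocks, feedback, startDelta,
#               sampleRate, amModRateHz, gapPosition
#   staircase:  rule ("2d1u" | "3d1u" | integer n), phases [[4, 2.0], ...],
#               startDelta, reversalThreshold, meanType, deltaMin, deltaMax,
#               maxTrials
#   observer:   model, alphaDelta, beta, gammaAuto or gamma, lambda, seed

cfg_field <- function(section, name, default = NULL, required = FALSE,
                      section_name = "") {
  if (!is.null(section[[name]])) return(section[[name]])
  if (required)
    stop("config error: required field '", section_name, ".", name,
         "' is missing", call. = FALSE)
  default
}

#' Read a session configuration file
#'
#' Parses a YAML (or JSON) configuration with `experiment`, `staircase`
#' and optional `observer` sections and builds the corresponding package
#' objects. Missing required fields raise an error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `experiment` ([experiment_spec()]), `staircase`
#'   ([staircase_config()]), `observer` ([psychometric_observer()] or
#'   `NULL`) and `observer_seed` (or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  ex <- raw$experiment
  if (is.null(ex)) stop("config error: section 'experiment' is missing",
                        call. = FALSE)
  name <- cfg_field(ex, "experiment", required = TRUE, section_name = "experiment")
  if (!name %in% EXPERIMENT_NAMES)
    stop("config error: experiment.experiment must be one of: ",
         paste(EXPERIMENT_NAMES, collapse = ", "), call. = FALSE)
  std <- NULL
  if (!is.null(ex$standard)) {
    s <- ex$standard
    tone_task <- name %in% c("freq_disc_tone", "intensity_disc_tone",
                             "duration_disc_tone")
    std <- if (tone_task)
      tone_spec(frequency = cfg_field(s, "frequencyHz", 1000),
                duration_ms = cfg_field(s, "durationMs", 250),
                level_dbfs = cfg_field(s, "levelDbfs", -20),
                ramp_ms = cfg_field(s, "rampMs", 10))
    else
      noise_spec(duration_ms = cfg_field(s, "durationMs", 500),
                 level_dbfs = cfg_field(s, "levelDbfs", -20),
                 ramp_ms = cfg_field(s, "rampMs", 10),
                 seed = cfg_field(s, "seed", 1L))
  }
  start_delta <- cfg_field(ex, "startDelta")
  spec <- experiment_spec(
    name, standard = std, start_delta = start_delta,
    n_afc = cfg_field(ex, "nAfc", 3L),
    isi_ms = cfg_field(ex, "isiMs", 500),
    iti_ms = cfg_field(ex, "itiMs", 500),
    n_blocks = cfg_field(ex, "nBlocks", 1L),
    feedback = cfg_field(ex, "feedback", TRUE),
    sample_rate = cfg_field(ex, "sampleRate", 48000),
    am_mod_rate_hz = cfg_field(ex, "amModRateHz", 20),
    gap_position = cfg_field(ex, "gapPosition", "center"))

  st <- raw$staircase
  if (is.null(st)) stop("config error: section 'staircase' is missing",
                        call. = FALSE)
  phases <- cfg_field(st, "phases", list(c(4, 2), c(8, sqrt(2))))
  if (is.matrix(phases))  # jsonlite may simplify [[4,2],[8,1.41]] to a matrix
    phases <- lapply(seq_len(nrow(phases)), function(i) phases[i, ])
  sd0 <- cfg_field(st, "startDelta", spec$start_delta)
  # default staircase bounds stay inside the experiment's stimulus range
  config <- staircase_config(
    n_down = cfg_field(st, "rule", required = TRUE, section_name = "staircase"),
    phases = phases,
    start_delta = sd0,
    reversal_threshold_k = cfg_field(st, "reversalThreshold", 8L),
    mean_type = cfg_field(st, "meanType", "arithmetic"),
    delta_min = cfg_field(st, "deltaMin",
                          max(sd0 / 1e4, spec$delta_bounds[1])),
    delta_max = cfg_field(st, "deltaMax",
                          min(sd0 * 1e2, spec$delta_bounds[2])),
    max_trials = cfg_field(st, "maxTrials", 1000L))

  obs <- NULL; obs_seed <- NULL
  if (!is.null(raw$observer)) {
    o <- raw$observer
    gamma <- if (isTRUE(o$gammaAuto) || is.null(o$gamma)) 1 / spec$n_afc
             else o$gamma
    obs <- psychometric_observer(
      alpha = cfg_field(o, "alphaDelta", required = TRUE,
                        section_name = "observer"),
      beta = cfg_field(o, "beta", required = TRUE, section_name = "observer"),
      gamma = gamma,
      lambda = cfg_field(o, "lambda", 0),
      model = cfg_field(o, "model", "logistic"))
    obs_seed <- o$seed
  }
  list(experiment = spec, staircase = config, observer = obs,
       observer_seed = obs_seed)
}
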