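# Transformed up-down (n-down/one-up) staircase engine.
#
# The staircase adaptively varies a stimulus difference ("delta"): after
# n_down consecutive correct responses delta is divided by the step factor
# in force; after any incorrect response it is multiplied by the same
# factor. A change of stepping direction is a reversal; the threshold is
# estimated from the deltas logged at the final reversals.

#' Configure a transformed up-down staircase
#'
#' Defines an n-down/one-up adaptive rule with multiplicative steps. The
#' rule divides delta by the phase factor after `n_down` consecutive
#' correct responses and multiplies it by the same factor after every
#' incorrect response. The two-down/one-up rule converges on the stimulus
#' difference yielding 70.7% correct; three-down/one-up converges on 79.4%
#' (see [equilibrium_probability()]).
#'
#' Step factors are organised in phases keyed to the reversal count: a
#' large factor early to approach the threshold quickly, then a small one
#' for fine estimation. The default — four reversals at factor 2 followed
#' by eight at sqrt(2), threshold on the last eight — is the classic
#' laboratory configuration.
#'
#' @param n_down Number of consecutive correct responses required for a
#'   down step. 2 and 3 are the usual choices; any integer >= 1 is
#'   accepted.
#' @param phases List of `c(reversal_count, factor)` pairs, in order. The
#'   factors must all exceed 1; the reversal counts sum to the total
#'   number of reversals collected before the track terminates.
#' @param start_delta Delta presented on the first trial, in experiment
#'   units (Hz, dB, ms or percent). Choose it high enough that the first
#'   trials are easy.
#' @param reversal_threshold_k Number of final reversals averaged into the
#'   threshold. An even number is recommended (odd values are accepted
#'   with a warning) so that peaks and valleys are balanced.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` averaging of
#'   the reversal deltas.
#' @param delta_min,delta_max Hard bounds on delta; steps are clamped (not
#'   rejected) at the bounds and clamping events are counted.
#' @param max_trials Safety cap on the number of trials per track.
#' @return An object of class `staircase_config`.
#' @seealso [new_track()], [update_track()], [threshold_last_k()]
#' @examples
#' cfg <- staircase_config(n_down = 2, start_delta = 100)
#' cfg
#' @export
staircase_config <- function(n_down = 2L,
                             phases = list(c(4, 2), c(8, sqrt(2))),
                             start_delta,
                             reversal_threshold_k = 8L,
                             mean_type = c("arithmetic", "geometric"),
                             delta_min = start_delta / 1e4,
                             delta_max = start_delta * 1e2,
                             max_trials = 1000L) {
  mean_type <- match.arg(mean_type)
  n_down <- parse_rule(n_down)
  if (!is.list(phases) || length(phases) < 1L)
    stop("'phases' must be a non-empty list of c(reversal_count, factor) pairs")
  counts <- vapply(phases, function(p) as.integer(p[[1]]), integer(1))
  factors <- vapply(phases, function(p) as.numeric(p[[2]]), numeric(1))
  if (any(counts < 1L)) stop("phase reversal counts must be positive integers")
  if (any(factors <= 1)) stop("every step factor must be > 1")
  total <- sum(counts)
  if (!is.numeric(start_delta) || length(start_delta) != 1L || start_delta <= 0)
    stop("'start_delta' must be a single positive number")
  reversal_threshold_k <- as.integer(reversal_threshold_k)
  if (reversal_threshold_k < 1L || reversal_threshold_k > total)
    stop("'reversal_threshold_k' must be between 1 and the total reversal count (",
         total, ")")
  if (reversal_threshold_k %% 2L == 1L)
    warning("an even number of reversals is recommended for the threshold ",
            "to balance peaks and valleys", call. = FALSE)
  if (delta_min <= 0 || delta_max <= 0 || delta_min > delta_max)
    stop("'delta_min' and 'delta_max' must be positive with delta_min <= delta_max")
  if (start_delta < delta_min || start_delta > delta_max)
    stop("'start_delta' must lie within [delta_min, delta_max]")
  max_trials <- as.integer(max_trials)
  if (max_trials < 1L) stop("'max_trials' must be a positive integer")
  structure(list(
    n_down = n_down,
    phase_counts = counts,
    phase_factors = factors,
    phase_bounds = cumsum(counts),
    total_reversals = total,
    start_delta = as.numeric(start_delta),
    reversal_threshold_k = reversal_threshold_k,
    mean_type = mean_type,
    delta_min = as.numeric(delta_min),
    delta_max = as.numeric(delta_max),
    max_trials = max_trials
  ), class = "staircase_config")
}

# Accepts 2, "2", "2d1u", "3d1u" etc.
parse_rule <- function(rule) {
  if (is.character(rule)) {
    m <- regmatches(rule, regexec("^([0-9]+)d1u$", rule))[[1]]
    if (length(m) == 2L) rule <- as.integer(m[2]) else rule <- suppressWarnings(as.integer(rule))
  }
  rule <- as.integer(rule)
  if (is.na(rule) || rule < 1L)
    stop("the staircase rule must be an integer n >= 1 (n-down/one-up), ",
         "or a string like \"2d1u\"")
  rule
}

#' @export
print.staircase_config <- function(x, ...) {
  cat(sprintf("%d-down/1-up staircase (tracks %.1f%% correct)\n",
              x$n_down, 100 * equilibrium_probability(x$n_down)))
  cat(sprintf("  phases: %s\n",
              paste(sprintf("%d reversals @ factor %.4g", x$phase_counts,
                            x$phase_factors), collapse = ", ")))
  cat(sprintf("  start delta %.4g in [%.4g, %.4g]; threshold on last %d reversals (%s mean)\n",
              x$start_delta, x$delta_min, x$delta_max,
              x$reversal_threshold_k, x$mean_type))
  invisible(x)
}

#' Initialise a staircase track
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_track` holding the current delta,
#'   the consecutive-correct counter, the last stepping direction, the
#'   reversal ledger (trial index and the delta presented on the trial
#'   that triggered the direction change), the trial count, the response
#'   log and the finished flag.
#' @export
new_track <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(
    delta = config$start_delta,
    consecutive_correct = 0L,
    last_direction = "none",
    reversal_trial = integer(0),
    reversal_delta = numeric(0),
    trial_count = 0L,
    responses = logical(0),
    n_clamped = 0L,
    finished = FALSE
  ), class = "staircase_track")
}

#' Step factor currently in force
#'
#' Returns the factor of the phase that the *next* reversal falls in:
#' once the i-th reversal has been recorded, steps on subsequent trials
#' use the phase containing reversal i + 1. With the default phases (4
#' reversals at factor 2, then 8 at sqrt(2)), every trial after the one
#' on which the fourth reversal is recorded steps by the small factor.
#' Within [update_track()] the factor is fixed at trial onset, so the
#' step on the boundary trial itself still uses the old phase's factor.
#'
#' @param state A `staircase_track`.
#' @param config The matching `staircase_config`.
#' @return A single numeric factor.
#' @export
current_factor <- function(state, config) {
  idx <- length(state$reversal_delta) + 1L
  phase <- which(idx <= config$phase_bounds)[1]
  if (is.na(phase)) phase <- length(config$phase_factors)
  config$phase_factors[phase]
}

#' Advance a staircase track by one response
#'
#' Applies the n-down/one-up rule. A correct response increments the
#' consecutive-correct counter; when the counter reaches `n_down` a down
#' step divides delta by the factor in force and resets the counter. An
#' incorrect response triggers an up step (multiply by the factor) and
#' resets the counter. A step whose direction differs from the previous
#' step's direction records a reversal, logged with the delta presented on
#' the triggering trial (the pre-step value). The first step of a track
#' never records a reversal.
#'
#' Delta is clamped to `[delta_min, delta_max]`; a clamped step still
#' counts for direction and reversal logic. The track finishes the moment
#' the final reversal is recorded (no step is applied after it) or when
#' `max_trials` is reached.
#'
#' @param state A `staircase_track` that is not finished.
#' @param config The matching `staircase_config`.
#' @param correct Logical, whether the response was correct.
#' @return The updated `staircase_track`.
#' @examples
#' cfg <- staircase_config(2, phases = list(c(6, 2)), start_delta = 100,
#'                         reversal_threshold_k = 4)
#' tr <- new_track(cfg)
#' for (r in c(TRUE, TRUE, TRUE, TRUE, FALSE)) tr <- update_track(tr, cfg, r)
#' tr$reversal_delta  # 25: first direction change, logged pre-step
#' @export
update_track <- function(state, config, correct) {
  if (state$finished)
    stop("cannot update a finished staircase track", call. = FALSE)
  correct <- isTRUE(correct)
  state$trial_count <- state$trial_count + 1L
  state$responses[state$trial_count] <- correct

  step <- NULL
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$n_down) {
      state$consecutive_correct <- 0L
      step <- "down"
    }
  } else {
    state$consecutive_correct <- 0L
    step <- "up"
  }

  if (!is.null(step)) {
    # the factor in force is fixed at trial onset; a reversal recorded on
    # this trial only changes the factor from the next trial on
    fac <- current_factor(state, config)
    if (state$last_direction != "none" && state$last_direction != step) {
      i <- length(state$reversal_delta) + 1L
      state$reversal_trial[i] <- state$trial_count
      state$reversal_delta[i] <- state$delta
    }
    if (length(state$reversal_delta) >= config$total_reversals) {
      state$finished <- TRUE
    } else {
      new_delta <- if (step == "down") state$delta / fac else state$delta * fac
      if (new_delta < config$delta_min || new_delta > config$delta_max)
        state$n_clamped <- state$n_clamped + 1L
      state$delta <- min(max(new_delta, config$delta_min), config$delta_max)
    }
    state$last_direction <- step
  }

  if (!state$finished && state$trial_count >= config$max_trials)
    state$finished <- TRUE
  state
}

#' @export
print.staircase_track <- function(x, ...) {
  cat(sprintf("staircase track: %d trials, %d reversals, delta %.4g%s\n",
              x$trial_count, length(x$reversal_delta), x$delta,
              if (x$finished) " [finished]" else ""))
  invisible(x)
}

threshold_estimate <- function(value, method, n_reversals_used, complete = TRUE) {
  structure(list(value = value, method = method,
                 n_reversals_used = as.integer(n_reversals_used),
                 complete = isTRUE(complete)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold %.4g (%s over %d reversals%s)\n", x$value, x$method,
              x$n_reversals_used, if (x$complete) "" else "; track incomplete"))
  invisible(x)
}

#' Threshold from the last k reversals
#'
#' The classic reversal-based estimate: the arithmetic (or geometric) mean
#' of the deltas logged at the final `k` reversals — normally those run
#' with the small step factor. An even `k` is recommended so peaks and
#' valleys contribute equally; odd values are accepted with a warning.
#'
#' @param reversals Numeric vector of reversal deltas, in track order.
#' @param k Number of final reversals to average.
#' @param mean_type `"arithmetic"` or `"geometric"`.
#' @param complete Passed through to the estimate (FALSE when the track
#'   hit its trial cap before collecting all reversals).
#' @return A `threshold_estimate`.
#' @examples
#' threshold_last_k(c(100, 50, 25, 40, 20, 40, 20, 40, 20, 40, 20, 40), k = 6)
#' @export
threshold_last_k <- function(reversals, k,
                             mean_type = c("arithmetic", "geometric"),
                             complete = TRUE) {
  mean_type <- match.arg(mean_type)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1")
  if (k > length(reversals))
    stop("insufficient data: ", length(reversals), " reversals available, ",
         k, " requested")
  if (k %% 2L == 1L)
    warning("an even number of reversals is recommended for the threshold",
            call. = FALSE)
  r <- reversals[(length(reversals) - k + 1L):length(reversals)]
  value <- if (mean_type == "geometric") exp(mean(log(r))) else mean(r)
  threshold_estimate(value, "last_k_mean", k, complete)
}

#' Threshold from midpoints of runs
#'
#' A run is a stretch of steps in one direction, bounded by two
#' reversals; its midpoint is the arithmetic mean of the bounding
#' reversal deltas. This estimator takes the final `n_used` reversals,
#' forms the midpoints of consecutive pairs, and averages them.
#'
#' @param reversals Numeric vector of reversal deltas, in track order.
#' @param n_used Even number of final reversals to use (an odd number is
#'   an error: estimating on an even number of reversals reduces bias).
#' @param mean_type `"arithmetic"` or `"geometric"` mean of the midpoints.
#' @return A `threshold_estimate`.
#' @examples
#' threshold_midpoint_runs(c(16, 32, 8, 24), n_used = 4)  # midpoints 24,20,16
#' @export
threshold_midpoint_runs <- function(reversals, n_used,
                                    mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  n_used <- as.integer(n_used)
  if (n_used < 2L) stop("'n_used' must be at least 2")
  if (n_used %% 2L == 1L)
    stop("'n_used' must be even: thresholds should be computed on an even ",
         "number of reversals to reduce estimation bias")
  if (n_used > length(reversals))
    stop("insufficient data: ", length(reversals), " reversals available, ",
         n_used, " requested")
  r <- reversals[(length(reversals) - n_used + 1L):length(reversals)]
  mid <- (r[-length(r)] + r[-1L]) / 2
  value <- if (mean_type == "geometric") exp(mean(log(mid))) else mean(mid)
  threshold_estimate(value, "midpoint_of_runs", n_used, TRUE)
}

#' Performance level tracked by an n-down/one-up rule
#'
#' At equilibrium the probability of a down step (p^n, n consecutive
#' correct responses) equals the probability of an up step, so the track
#' oscillates around the stimulus level where p^n = 1/2. Solving gives
#' p = 0.5^(1/n): 70.7% correct for the two-down/one-up rule, 79.4% for
#' three-down/one-up, 84.1% for four-down/one-up.
#'
#' @param n_down Integer (vectorised) rule order, >= 1.
#' @return The tracked proportion correct, 0.5^(1/n_down).
#' @examples
#' equilibrium_probability(2:4)
#' @export
equilibrium_probability <- function(n_down) {
  n_down <- as.integer(n_down)
  if (any(is.na(n_down)) || any(n_down < 1L))
    stop("'n_down' must be an integer >= 1")
  0.5^(1 / n_down)
}

#' Compute the threshold of a finished track
#'
#' Convenience wrapper applying the configured estimator to a track's
#' reversal ledger. If the track hit `max_trials` before collecting all
#' reversals, the threshold is computed on the reversals available (with
#' a warning) and flagged incomplete; a track with fewer than one usable
#' reversal yields `NA`.
#'
#' @param state A finished `staircase_track`.
#' @param config The matching `staircase_config`.
#' @return A `threshold_estimate`.
#' @export
track_threshold <- function(state, config) {
  n_rev <- length(state$reversal_delta)
  complete <- n_rev >= config$total_reversals
  k <- min(config$reversal_threshold_k, n_rev)
  if (!complete)
    warning(sprintf(paste0("track stopped at the trial cap with %d of %d ",
                           "reversals; threshold computed on %d"),
                    n_rev, config$total_reversals, k), call. = FALSE)
  if (k < 1L)
    return(threshold_estimate(NA_real_, "last_k_mean", 0L, FALSE))
  suppressWarnings(
    threshold_last_k(state$reversal_delta, k, config$mean_type,
                     complete = complete)
  )
}
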