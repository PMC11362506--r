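# Simulated listeners: parametric psychometric functions that answer
# forced-choice trials, used for closed-loop validation of the staircases.

#' Simulated observer with a parametric psychometric function
#'
#' The probability of a correct response at stimulus difference delta is
#' `Psi(delta) = gamma + (1 - gamma - lambda) * F(delta)` where `gamma` is
#' the guess floor (chance level, 1/n_afc in an nAFC task), `lambda` the
#' lapse rate, and `F` either a logistic in log-delta,
#' `F = 1 / (1 + exp(-beta * (log(delta) - log(alpha))))`, or a Weibull,
#' `F = 1 - exp(-(delta / alpha)^beta)`. The log-delta logistic is the
#' default: its natural axis matches the multiplicative step geometry of
#' the staircase.
#'
#' `alpha = Inf` gives a zero-sensitivity observer with `Psi == gamma`
#' at every delta (see [chance_observer()]).
#'
#' @param alpha Threshold location in delta units (> 0, or `Inf`).
#' @param beta Slope (> 0) on the log-delta (logistic) or log-log
#'   (Weibull) axis.
#' @param gamma Guess floor in `[0, 1)`.
#' @param lambda Lapse rate in `[0, 0.1]`; defaults to 0.
#' @param model `"logistic"` or `"weibull"`.
#' @return An object of class `psychometric_observer`.
#' @examples
#' obs <- psychometric_observer(alpha = 10, beta = 4, gamma = 1/3)
#' p_correct(obs, 10)  # gamma + (1 - gamma)/2 = 2/3
#' @export
psychometric_observer <- function(alpha, beta, gamma = 1/3, lambda = 0,
                                  model = c("logistic", "weibull")) {
  model <- match.arg(model)
  if (!(alpha > 0)) stop("'alpha' must be positive (Inf allowed)")
  if (!(beta > 0)) stop("'beta' must be positive")
  if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
  if (lambda < 0 || lambda > 0.1) stop("'lambda' must lie in [0, 0.1]")
  if (gamma + lambda >= 1) stop("gamma + lambda must be < 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
                 model = model),
            class = "psychometric_observer")
}

#' Zero-sensitivity observer
#'
#' An observer whose probability correct equals the chance floor
#' `1/n_afc` at every delta — it can only guess. Useful for checking
#' floor performance and staircase clamping.
#'
#' @param n_afc Number of alternatives.
#' @return A `psychometric_observer` with `Psi == 1/n_afc`.
#' @export
chance_observer <- function(n_afc) {
  psychometric_observer(alpha = Inf, beta = 1, gamma = 1 / n_afc)
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat(sprintf("%s observer: alpha %.4g, beta %.4g, gamma %.4g, lambda %.4g\n",
              x$model, x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

#' Probability of a correct response
#'
#' Evaluates the observer's psychometric function (vectorised over
#' `delta`).
#'
#' @param obs A [psychometric_observer()].
#' @param delta Positive stimulus difference(s).
#' @return Probability (or vector of probabilities) in
#'   `[gamma, 1 - lambda]`.
#' @export
p_correct <- function(obs, delta) {
  stopifnot(inherits(obs, "psychometric_observer"))
  if (any(!(delta > 0))) stop("'delta' must be positive")
  f <- if (is.infinite(obs$alpha)) {
    rep(0, length(delta))
  } else if (obs$model == "logistic") {
    1 / (1 + exp(-obs$beta * (log(delta) - log(obs$alpha))))
  } else {
    1 - exp(-(delta / obs$alpha)^obs$beta)
  }
  obs$gamma + (1 - obs$gamma - obs$lambda) * f
}

#' Simulated response to a trial
#'
#' With probability `Psi(delta)` the observer picks the target interval;
#' otherwise it picks uniformly among the non-target intervals. Uses the
#' caller's RNG stream, so a fixed seed gives a fixed response sequence.
#'
#' @param obs A [psychometric_observer()].
#' @param trial A [make_trial()] result.
#' @return The 1-based chosen interval index.
#' @export
respond <- function(obs, trial) {
  stopifnot(inherits(trial, "trial"))
  p <- p_correct(obs, trial$delta)
  if (stats::runif(1) < p) {
    trial$target_index
  } else {
    others <- seq_len(trial$n_afc)[-trial$target_index]
    if (length(others) == 1L) others else others[sample.int(length(others), 1L)]
  }
}

#' Wrap an observer as a block responder
#'
#' @param obs A [psychometric_observer()].
#' @return A function `trial -> response index`, usable with
#'   [run_block()] and [run_session()].
#' @export
observer_responder <- function(obs) {
  force(obs)
  function(trial) respond(obs, trial)
}

#' Empirically tracked performance of a staircase rule
#'
#' Runs `n_replicates` complete closed-loop tracks (trial assembly,
#' simulated response, scoring, staircase update), estimates each track's
#' threshold from its final reversals, and evaluates the observer's true
#' psychometric function at each threshold estimate. The mean of
#' `Psi(threshold)` is the performance level the rule empirically tracks;
#' for an n-down/one-up rule it should approach
#' [equilibrium_probability()]`(n)` (70.7% for n = 2, 79.4% for n = 3),
#' with a small upward bias at finite step size and track length.
#'
#' @param config A [staircase_config()].
#' @param spec An [experiment_spec()].
#' @param obs A [psychometric_observer()] whose `gamma` should equal
#'   `1/spec$n_afc`.
#' @param n_replicates Number of simulated tracks (>= 1).
#' @param seed Optional seed applied once before the first track.
#' @return An object of class `tracked_performance`: vectors `threshold`
#'   and `psi` (one entry per replicate), their means and SDs, and the
#'   analytic equilibrium for comparison.
#' @examples
#' \donttest{
#' sp <- experiment_spec("freq_disc_tone")
#' cfg <- staircase_config(2, start_delta = 100)
#' obs <- psychometric_observer(10, 4, gamma = 1/3)
#' tracked_performance(cfg, sp, obs, n_replicates = 100, seed = 1)
#' }
#' @export
tracked_performance <- function(config, spec, obs, n_replicates, seed = NULL) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(spec, "experiment_spec"),
            inherits(obs, "psychometric_observer"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("'n_replicates' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  responder <- observer_responder(obs)
  thr <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    blk <- run_block(spec, config, responder, record = FALSE)
    thr[i] <- blk$result$threshold$value
  }
  psi <- p_correct(obs, thr)
  structure(list(
    threshold = thr, psi = psi,
    mean_threshold = mean(thr), sd_threshold = stats::sd(thr),
    mean_psi = mean(psi), sd_psi = stats::sd(psi),
    equilibrium = equilibrium_probability(config$n_down),
    n_replicates = n_replicates
  ), class = "tracked_performance")
}

#' @export
print.tracked_performance <- function(x, ...) {
  cat(sprintf("tracked performance over %d tracks:\n", x$n_replicates))
  cat(sprintf("  mean threshold %.4g (SD %.4g)\n", x$mean_threshold,
              x$sd_threshold))
  cat(sprintf("  mean Psi(threshold) %.3f (SD %.3f); analytic equilibrium %.3f\n",
              x$mean_psi, x$sd_psi, x$equilibrium))
  invisible(x)
}
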