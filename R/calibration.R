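# Lean batch runner for Monte-Carlo work. Draws the same random-number
# stream as run_session() (one uniform for the reflector state, one for the
# response, per trial) so the two paths are bit-identical under equal seeds;
# test-calibration.R asserts this.
siam_threshold_batch <- function(n_sessions, observer,
                                 config = staircase_config(),
                                 start_distance = config$start_distance) {
  stopifnot(inherits(observer, "echo_observer"), n_sessions >= 1L)
  random <- inherits(observer, "random_observer")
  p_yes <- if (random) observer$p_yes else NA_real_
  crit <- if (random) NA_real_ else observer$criterion

  grid <- config$grid_step
  d_min <- config$d_min
  n_grid <- config$n_grid
  start_idx <- snap_to_grid(start_distance, config)
  su <- config$steps_units # hit, miss, correct_rejection, false_alarm
  s_hit <- su[1L]; s_miss <- su[2L]; s_cr <- su[3L]; s_fa <- su[4L]
  n_stop <- config$n_reversals_stop
  n_avg <- config$n_reversals_avg
  max_t <- config$max_trials
  p_reflect <- config$p_reflect
  # precompute p(yes) on the distance grid for SDT observers
  if (!random) {
    dgrid <- d_min + (0:n_grid) * grid
    dp <- dprime_at(observer, dgrid)
    p_yes_refl <- stats::pnorm(dp / 2 - crit)
    p_yes_non <- stats::pnorm(-dp / 2 - crit)
  }

  thresholds <- numeric(n_sessions)
  revs <- numeric(n_stop)
  for (s in seq_len(n_sessions)) {
    idx <- start_idx
    n_rev <- 0L
    last_dir <- 0L
    t <- 0L
    while (n_rev < n_stop && t < max_t) {
      t <- t + 1L
      reflecting <- stats::runif(1) < p_reflect
      p <- if (random) p_yes
           else if (reflecting) p_yes_refl[idx + 1L] else p_yes_non[idx + 1L]
      yes <- stats::runif(1) < p
      st <- if (reflecting) {
        if (yes) s_hit else s_miss
      } else {
        if (yes) s_fa else s_cr
      }
      idx <- min(n_grid, max(0L, idx + st))
      if (st != 0L) {
        dir <- if (st > 0L) 1L else -1L
        if (last_dir != 0L && dir != last_dir) {
          n_rev <- n_rev + 1L
          revs[n_rev] <- d_min + idx * grid
        }
        last_dir <- dir
      }
    }
    thresholds[s] <- if (n_rev >= n_avg) {
      mean(revs[(n_rev - n_avg + 1L):n_rev])
    } else if (n_rev > 0L) {
      mean(revs[seq_len(n_rev)])
    } else {
      d_min + idx * grid
    }
  }
  thresholds
}

#' Monte-Carlo chance-level calibration of the SIAM staircase
#'
#' Simulates `n_reps` independent "participants", each completing
#' `sessions_per_rep` staircase sessions with a stimulus-independent
#' responder, and returns central percentile intervals of both the pooled
#' single-session thresholds and the per-participant session means. These
#' intervals characterise where threshold estimates of an observer who cannot
#' do the task at all will fall, and so define the chance band against which
#' real participants are judged.
#'
#' @param config A [staircase_config()].
#' @param n_reps Number of simulated participants (at least 1000 for stable
#'   percentiles).
#' @param sessions_per_rep Sessions per simulated participant.
#' @param seed Optional integer seed.
#' @param level Coverage of the central interval (default 95%).
#' @param observer Response model; defaults to an unbiased coin-flip
#'   responder.
#' @return An object of class `siam_calibration`: a list with the pooled
#'   `single_session_thresholds`, the per-participant `mean_thresholds`,
#'   their central percentile intervals `interval_single` and
#'   `interval_mean`, and run metadata. Percentiles use the empirical
#'   quantile with linear interpolation ([stats::quantile()] type 7).
#' @examples
#' \donttest{
#' cal <- calibrate_random_responder(n_reps = 1000, seed = 1)
#' cal$interval_mean
#' }
#' @export
calibrate_random_responder <- function(config = staircase_config(),
                                       n_reps = 10000L,
                                       sessions_per_rep = 12L,
                                       seed = NULL, level = 0.95,
                                       observer = random_observer(0.5)) {
  stopifnot(n_reps >= 1L, sessions_per_rep >= 1L, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  th <- siam_threshold_batch(n_reps * sessions_per_rep, observer, config)
  means <- colMeans(matrix(th, nrow = sessions_per_rep))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(
    list(
      single_session_thresholds = th,
      mean_thresholds = means,
      interval_single = stats::quantile(th, probs, names = FALSE),
      interval_mean = stats::quantile(means, probs, names = FALSE),
      n_reps = as.integer(n_reps),
      sessions_per_rep = as.integer(sessions_per_rep),
      level = level, seed = seed, config = config
    ),
    class = "siam_calibration"
  )
}

#' @export
print.siam_calibration <- function(x, ...) {
  cat(sprintf("Chance-level calibration (%d participants x %d sessions)\n",
              x$n_reps, x$sessions_per_rep))
  cat(sprintf("  central %.0f%% interval of session means: [%.3f, %.3f] m\n",
              100 * x$level, x$interval_mean[1], x$interval_mean[2]))
  cat(sprintf("  central %.0f%% interval of single sessions: [%.3f, %.3f] m\n",
              100 * x$level, x$interval_single[1], x$interval_single[2]))
  invisible(x)
}

#' Threshold recovery for a sensitivity-parameterised observer
#'
#' Runs `n_sessions` independent staircase sessions for an observer with a
#' known sensitivity profile and summarises the session thresholds. The
#' summary reports two reference distances: the distance where d' crosses
#' 1.0 (the level the procedure is nominally described as targeting) and the
#' staircase's true drift-zero distance from [siam_target_distance()], where
#' reversal-averaged thresholds actually concentrate once the start-up
#' transient has decayed (see the methods vignette).
#'
#' @param observer An [sdt_observer()] whose d' crosses 1.0 strictly inside
#'   the rail; otherwise a warning is issued and the recovery sits near a
#'   bound.
#' @param config A [staircase_config()].
#' @param n_sessions Number of sessions to simulate.
#' @param seed Optional integer seed.
#' @param start_distance Start distance for every session; defaults to the
#'   configured start.
#' @return An object of class `siam_recovery`: list with `thresholds`,
#'   `mean_threshold`, `sd_threshold`, `dprime1_distance`,
#'   `drift_zero_distance`, `n_sessions`.
#' @export
recover_threshold_distance <- function(observer,
                                       config = staircase_config(),
                                       n_sessions = 200L, seed = NULL,
                                       start_distance = config$start_distance) {
  stopifnot(inherits(observer, "echo_observer"), n_sessions >= 1L)
  if (!is.null(seed)) set.seed(seed)
  cross <- if (inherits(observer, "sdt_observer")) {
    dprime_crossing(observer, 1.0, c(config$d_min, config$d_max))
  } else {
    NA_real_
  }
  if (is.na(cross) || cross <= config$d_min || cross >= config$d_max) {
    warning("observer sensitivity does not cross d' = 1 inside the rail; ",
            "recovered thresholds will sit near a bound or the chance band")
  }
  th <- siam_threshold_batch(n_sessions, observer, config, start_distance)
  structure(
    list(
      thresholds = th,
      mean_threshold = mean(th),
      sd_threshold = stats::sd(th),
      dprime1_distance = cross,
      drift_zero_distance = suppressWarnings(
        siam_target_distance(observer, config)),
      n_sessions = as.integer(n_sessions)
    ),
    class = "siam_recovery"
  )
}

#' @export
print.siam_recovery <- function(x, ...) {
  cat(sprintf("Threshold recovery over %d sessions\n", x$n_sessions))
  cat(sprintf("  mean threshold: %.3f m (sd %.3f)\n",
              x$mean_threshold, x$sd_threshold))
  cat(sprintf("  d' = 1 crossing: %.3f m; staircase drift-zero: %.3f m\n",
              x$dprime1_distance, x$drift_zero_distance))
  invisible(x)
}
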