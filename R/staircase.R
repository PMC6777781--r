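#' SIAM staircase configuration
#'
#' Parameterises the single-interval adjustment-matrix (SIAM) yes--no
#' staircase as run on a motorised rail: the reflector can stop anywhere on a
#' 0.5 cm grid between `d_min` and `d_max`, and each trial outcome moves it by
#' a fixed amount. The default step matrix (+0.25 m on a hit, -0.25 m on a
#' miss, 0 on a correct rejection, -0.50 m on a false alarm) is the t = 0.5
#' SIAM variant: larger distances are harder, so hits push the task harder and
#' errors push it easier, with false alarms penalised twice as hard.
#'
#' A session stops once `n_reversals_stop` reversals of the movement
#' direction have occurred, and the threshold is the arithmetic mean of the
#' last `n_reversals_avg` reversal distances.
#'
#' @param d_min,d_max Rail limits in metres.
#' @param grid_step Spatial resolution of the rail in metres. All step sizes
#'   must be integer multiples of this.
#' @param start_distance Distance of the first trial in metres. Defaults to
#'   the closest (easiest) position, where participants are trained.
#' @param step_hit,step_miss,step_cr,step_fa Signed distance change in metres
#'   applied after each of the four trial outcomes.
#' @param n_reversals_stop Number of direction reversals that ends a session.
#' @param n_reversals_avg Number of final reversals averaged into the
#'   threshold estimate.
#' @param p_reflect Probability that a trial presents the reflector in
#'   reflecting mode (independent Bernoulli draw per trial).
#' @param max_trials Safety cap on trials per session; only reached by
#'   degenerate responders that never accumulate reversals.
#' @return An object of class `staircase_config`.
#' @seealso [run_session()], [next_distance()], [threshold_from_reversals()]
#' @examples
#' cfg <- staircase_config()
#' next_distance(1.50, "false_alarm", cfg)
#' @export
staircase_config <- function(d_min = 0.7, d_max = 3.9, grid_step = 0.005,
                             start_distance = d_min,
                             step_hit = 0.25, step_miss = -0.25,
                             step_cr = 0, step_fa = -0.50,
                             n_reversals_stop = 12L, n_reversals_avg = 10L,
                             p_reflect = 0.5, max_trials = 500L) {
  stopifnot(
    is.numeric(d_min), is.numeric(d_max), length(d_min) == 1L,
    length(d_max) == 1L, d_min < d_max,
    is.numeric(grid_step), length(grid_step) == 1L, grid_step > 0,
    start_distance >= d_min, start_distance <= d_max,
    n_reversals_avg >= 1L, n_reversals_stop >= n_reversals_avg,
    p_reflect > 0, p_reflect < 1, max_trials >= 1L
  )
  steps <- c(hit = step_hit, miss = step_miss,
             correct_rejection = step_cr, false_alarm = step_fa)
  units <- steps / grid_step
  if (any(abs(units - round(units)) > 1e-8)) {
    stop("all step sizes must be integer multiples of `grid_step`")
  }
  span <- (d_max - d_min) / grid_step
  if (abs(span - round(span)) > 1e-8) {
    stop("`d_max - d_min` must be an integer multiple of `grid_step`")
  }
  structure(
    list(
      d_min = d_min, d_max = d_max, grid_step = grid_step,
      start_distance = start_distance,
      steps_m = steps,
      steps_units = as.integer(round(units)),
      n_grid = as.integer(round(span)),
      n_reversals_stop = as.integer(n_reversals_stop),
      n_reversals_avg = as.integer(n_reversals_avg),
      p_reflect = p_reflect,
      max_trials = as.integer(max_trials)
    ),
    class = "staircase_config"
  )
}

#' @export
print.staircase_config <- function(x, ...) {
  cat("SIAM staircase configuration\n")
  cat(sprintf("  rail: %.3f to %.3f m (grid %.3f m), start %.3f m\n",
              x$d_min, x$d_max, x$grid_step, x$start_distance))
  cat(sprintf("  steps [m]: hit %+.2f, miss %+.2f, CR %+.2f, FA %+.2f\n",
              x$steps_m[["hit"]], x$steps_m[["miss"]],
              x$steps_m[["correct_rejection"]], x$steps_m[["false_alarm"]]))
  cat(sprintf("  stop after %d reversals, threshold = mean of last %d\n",
              x$n_reversals_stop, x$n_reversals_avg))
  cat(sprintf("  p(reflecting) = %.2f, max %d trials\n",
              x$p_reflect, x$max_trials))
  invisible(x)
}

match_enum <- function(x, choices, arg = deparse(substitute(x))) {
  x <- as.character(x)
  bad <- !(x %in% choices)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (must be one of %s)",
                 arg, paste(unique(x[bad]), collapse = ", "),
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Classify a yes--no trial outcome
#'
#' Maps the 2 x 2 table of reflector state by response onto the four signal
#' detection outcome classes: a "yes" is a hit when the reflector was in
#' reflecting mode and a false alarm otherwise; a "no" is a miss when it was
#' reflecting and a correct rejection otherwise.
#'
#' @param disk_state `"reflecting"` or `"nonreflecting"` (vectorised).
#' @param response `"yes"` or `"no"` (vectorised).
#' @return Character vector with elements in `"hit"`, `"miss"`,
#'   `"correct_rejection"`, `"false_alarm"`.
#' @examples
#' classify_outcome("reflecting", "yes")
#' classify_outcome("nonreflecting", "yes")
#' @export
classify_outcome <- function(disk_state, response) {
  disk_state <- match_enum(disk_state, c("reflecting", "nonreflecting"),
                           "disk_state")
  response <- match_enum(response, c("yes", "no"), "response")
  ifelse(disk_state == "reflecting",
         ifelse(response == "yes", "hit", "miss"),
         ifelse(response == "yes", "false_alarm", "correct_rejection"))
}

snap_to_grid <- function(distance, config) {
  idx <- (distance - config$d_min) / config$grid_step
  ridx <- round(idx)
  if (any(abs(idx - ridx) > 1e-6) || any(ridx < 0) || any(ridx > config$n_grid)) {
    stop("distance is not on the staircase grid within the rail bounds")
  }
  as.integer(ridx)
}

idx_to_distance <- function(idx, config) config$d_min + idx * config$grid_step

#' Next reflector distance after a trial outcome
#'
#' Applies the SIAM step for `outcome` to `distance`, clipping at the rail
#' bounds (the physical rail cannot move further) and keeping the result on
#' the spatial grid.
#'
#' @param distance Current distance in metres (must lie on the grid).
#' @param outcome One of the four outcome classes, see [classify_outcome()].
#' @param config A [staircase_config()].
#' @return The next distance in metres.
#' @examples
#' next_distance(1.50, "false_alarm", staircase_config())  # 1.00
#' next_distance(0.70, "miss", staircase_config())         # clipped at 0.70
#' @export
next_distance <- function(distance, outcome, config = staircase_config()) {
  outcome <- match_enum(outcome, names(config$steps_m), "outcome")
  idx <- snap_to_grid(distance, config)
  step <- config$steps_units[match(outcome, names(config$steps_m))]
  idx_to_distance(pmin(config$n_grid, pmax(0L, idx + step)), config)
}

#' Flag direction reversals in a step history
#'
#' A reversal occurs when the latest non-zero movement direction differs from
#' the previous non-zero movement direction. Zero steps (correct rejections)
#' are transparent: they neither create nor destroy a pending direction.
#' Steps clipped at the rail bounds count with their intended sign, so a
#' responder pinned at a bound can still reverse.
#'
#' @param steps Numeric vector of signed (intended) per-trial steps.
#' @return Logical vector: `TRUE` at trials whose step reverses direction.
#' @examples
#' detect_reversals(c(0.25, 0.25, -0.25))       # FALSE FALSE TRUE
#' detect_reversals(c(0.25, 0, 0, 0.25))        # all FALSE
#' @export
detect_reversals <- function(steps) {
  stopifnot(is.numeric(steps))
  out <- logical(length(steps))
  last <- 0L
  for (i in seq_along(steps)) {
    s <- sign(steps[i])
    if (s != 0) {
      out[i] <- last != 0L && s != last
      last <- s
    }
  }
  out
}

#' Threshold from staircase reversals
#'
#' The session threshold is the arithmetic mean of the final `n_avg` reversal
#' distances.
#'
#' @param reversal_distances Numeric vector of reversal distances in metres,
#'   in the order they occurred.
#' @param n_avg Number of trailing reversals to average.
#' @param partial If `TRUE`, fewer than `n_avg` reversals are tolerated and
#'   all available ones are averaged (with a warning); otherwise this is an
#'   error.
#' @return Threshold in metres.
#' @examples
#' threshold_from_reversals(rep(2.40, 12))
#' threshold_from_reversals(1:12)  # mean of 3..12 = 7.5
#' @export
threshold_from_reversals <- function(reversal_distances, n_avg = 10L,
                                     partial = FALSE) {
  stopifnot(is.numeric(reversal_distances), n_avg >= 1L)
  n <- length(reversal_distances)
  if (n < n_avg) {
    if (!partial) {
      stop(sprintf("only %d reversals available but n_avg = %d", n, n_avg))
    }
    if (n == 0L) {
      warning("no reversals available; threshold is NA")
      return(NA_real_)
    }
    warning(sprintf("averaging all %d available reversals (n_avg = %d)",
                    n, n_avg))
  }
  mean(utils::tail(reversal_distances, n_avg))
}

#' Run one SIAM staircase session
#'
#' Simulates a full adaptive yes--no session: each trial draws the reflector
#' state (reflecting with probability `p_reflect`), queries the observer for a
#' response, classifies the outcome, moves the reflector by the corresponding
#' step (clipped to the rail), and flags direction reversals. The session
#' stops after `n_reversals_stop` reversals, or at `max_trials` for
#' degenerate responders.
#'
#' The distance logged for a reversal is the post-step distance, i.e. the
#' first distance of the new run direction, matching the behaviour of the
#' original experimental control script (see the methods vignette for how
#' this convention was validated against chance-level simulations). If the
#' trial cap is reached, the threshold is computed from the reversals
#' available so far, or falls back to the final distance when there are none.
#'
#' @param observer A response model, e.g. [random_observer()] or
#'   [sdt_observer()].
#' @param config A [staircase_config()].
#' @param seed Optional integer seed for reproducibility.
#' @param start_distance Override for the first trial's distance in metres.
#' @return An object of class `siam_session` with elements `trials` (a data
#'   frame with one row per trial), `reversal_distances`, `threshold`,
#'   `stopped_normally`, and the `config` and `observer` used.
#' @examples
#' s <- run_session(random_observer(), seed = 1)
#' s$threshold
#' @export
run_session <- function(observer, config = staircase_config(), seed = NULL,
                        start_distance = config$start_distance) {
  stopifnot(inherits(observer, "echo_observer"))
  if (!is.null(seed)) set.seed(seed)
  idx <- snap_to_grid(start_distance, config)
  n_stop <- config$n_reversals_stop
  max_t <- config$max_trials
  step_units <- config$steps_units
  outcomes <- names(config$steps_m)

  distance <- numeric(max_t)
  disk <- character(max_t)
  resp <- character(max_t)
  outc <- character(max_t)
  step_m <- numeric(max_t)
  is_rev <- logical(max_t)
  reversals <- numeric(n_stop)
  n_rev <- 0L
  last_dir <- 0L
  t <- 0L

  while (n_rev < n_stop && t < max_t) {
    t <- t + 1L
    d <- idx_to_distance(idx, config)
    state <- if (stats::runif(1) < config$p_reflect) "reflecting" else "nonreflecting"
    r <- respond(observer, d, state)
    o <- classify_outcome(state, r)
    s <- step_units[match(o, outcomes)]
    idx <- min(config$n_grid, max(0L, idx + s))

    distance[t] <- d
    disk[t] <- state
    resp[t] <- r
    outc[t] <- o
    step_m[t] <- s * config$grid_step

    if (s != 0L) {
      dir <- if (s > 0L) 1L else -1L
      if (last_dir != 0L && dir != last_dir) {
        is_rev[t] <- TRUE
        n_rev <- n_rev + 1L
        reversals[n_rev] <- idx_to_distance(idx, config)
      }
      last_dir <- dir
    }
  }

  stopped_normally <- n_rev == n_stop
  reversals <- reversals[seq_len(n_rev)]
  if (stopped_normally) {
    threshold <- threshold_from_reversals(reversals, config$n_reversals_avg)
  } else if (n_rev > 0L) {
    warning(sprintf(
      "session hit the %d-trial cap with %d reversal(s); threshold from available reversals",
      max_t, n_rev))
    threshold <- suppressWarnings(
      threshold_from_reversals(reversals, config$n_reversals_avg, partial = TRUE))
  } else {
    warning(sprintf(
      "session hit the %d-trial cap with no reversals; threshold set to final distance",
      max_t))
    threshold <- idx_to_distance(idx, config)
  }

  structure(
    list(
      trials = data.frame(
        index = seq_len(t), distance = distance[seq_len(t)],
        disk_state = disk[seq_len(t)], response = resp[seq_len(t)],
        outcome = outc[seq_len(t)], step_m = step_m[seq_len(t)],
        is_reversal = is_rev[seq_len(t)],
        stringsAsFactors = FALSE
      ),
      reversal_distances = reversals,
      threshold = threshold,
      stopped_normally = stopped_normally,
      config = config,
      observer = observer
    ),
    class = "siam_session"
  )
}

#' @export
print.siam_session <- function(x, ...) {
  cat(sprintf("SIAM session: %d trials, %d reversals%s\n",
              nrow(x$trials), length(x$reversal_distances),
              if (x$stopped_normally) "" else " (trial cap reached)"))
  cat(sprintf("  threshold estimate: %.3f m\n", x$threshold))
  invisible(x)
}

#' Plot a staircase session
#'
#' Distance against trial number, with reversal trials circled and the
#' threshold estimate as a dashed line.
#'
#' @param x A `siam_session`.
#' @param ... Passed to [plot()].
#' @export
plot.siam_session <- function(x, ...) {
  tr <- x$trials
  pch_map <- c(hit = 16, miss = 15, correct_rejection = 17, false_alarm = 25)
  plot(tr$index, tr$distance, type = "s", xlab = "Trial",
       ylab = "Distance [m]", ylim = c(x$config$d_min, x$config$d_max), ...)
  graphics::points(tr$index, tr$distance, pch = pch_map[tr$outcome], cex = 0.8)
  rev_idx <- which(tr$is_reversal)
  if (length(rev_idx)) {
    graphics::points(rev_idx, tr$distance[rev_idx], pch = 1, cex = 1.8)
  }
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
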