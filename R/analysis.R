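#' Running 1-ms windowed SPL trace
#'
#' Computes the sound pressure level of a recording over running rectangular
#' windows: for each window position the RMS level in dB is
#' `10 log10(mean(x^2)) + cal_db`. The default window is 1 ms and the hop is
#' one sample, the finest physically meaningful overlap at the recording's
#' sample rate.
#'
#' @param recording An `echo_recording`, or a numeric waveform (in which case
#'   `sample_rate` and `cal_db` must be supplied).
#' @param window_ms Window length in milliseconds.
#' @param hop_samples Hop between successive windows, in samples.
#' @param sample_rate,cal_db Used only when `recording` is a bare waveform.
#' @return Data frame of class `spl_trace` with columns `time_ms` (window
#'   start time) and `spl_db`.
#' @export
running_spl <- function(recording, window_ms = 1, hop_samples = 1L,
                        sample_rate = NULL, cal_db = 0) {
  if (inherits(recording, "echo_recording")) {
    x <- recording$samples
    sample_rate <- recording$sample_rate
    cal_db <- recording$cal_db
  } else {
    stopifnot(is.numeric(recording))
    if (is.null(sample_rate)) {
      stop("`sample_rate` is required for a bare waveform")
    }
    x <- recording
  }
  win <- round(window_ms / 1000 * sample_rate)
  if (win < 1L || win > length(x)) {
    stop("window does not fit inside the recording")
  }
  cs <- cumsum(c(0, x^2))
  starts <- seq.int(1L, length(x) - win + 1L, by = hop_samples)
  power <- (cs[starts + win] - cs[starts]) / win
  out <- data.frame(
    time_ms = (starts - 1L) / sample_rate * 1000,
    spl_db = 10 * log10(pmax(power, 1e-300)) + cal_db
  )
  attr(out, "window_ms") <- window_ms
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("spl_trace", "data.frame")
  out
}

#' Direct and reflected maxima of an SPL trace
#'
#' Takes the maximum windowed SPL in an initial window (the direct click)
#' and in a subsequent window (the reflected click), and forms the
#' inter-click interval (ICI) as the time separation between the two maxima.
#' Window membership is by window start time, in \[start, end); ties are
#' broken by the earliest time.
#'
#' @param spl_trace A trace from [running_spl()].
#' @param direct_window_ms Two-element window (ms) for the direct maximum.
#' @param reflected_window_ms Two-element window (ms) for the reflected
#'   maximum.
#' @return List with `direct_db`, `direct_time_ms`, `reflected_db`,
#'   `reflected_time_ms`, `ici_ms`.
#' @export
extract_maxima <- function(spl_trace, direct_window_ms = c(0, 3),
                           reflected_window_ms = c(3, 30)) {
  stopifnot(all(c("time_ms", "spl_db") %in% names(spl_trace)),
            length(direct_window_ms) == 2L, length(reflected_window_ms) == 2L,
            direct_window_ms[1] < direct_window_ms[2],
            reflected_window_ms[1] < reflected_window_ms[2])
  pick <- function(w, label) {
    sel <- spl_trace$time_ms >= w[1] & spl_trace$time_ms < w[2]
    if (!any(sel)) {
      stop(sprintf("the %s window [%g, %g) ms contains no SPL windows",
                   label, w[1], w[2]))
    }
    i <- which(sel)[which.max(spl_trace$spl_db[sel])]
    list(db = spl_trace$spl_db[i], time_ms = spl_trace$time_ms[i])
  }
  direct <- pick(direct_window_ms, "direct")
  reflected <- pick(reflected_window_ms, "reflected")
  list(
    direct_db = direct$db, direct_time_ms = direct$time_ms,
    reflected_db = reflected$db, reflected_time_ms = reflected$time_ms,
    ici_ms = reflected$time_ms - direct$time_ms
  )
}

#' Analyze one recording
#'
#' Runs [running_spl()] and [extract_maxima()] and returns a one-row data
#' frame.
#'
#' @param recording An `echo_recording`.
#' @param ... Passed to [extract_maxima()].
#' @param window_ms,hop_samples Passed to [running_spl()].
#' @return One-row data frame with `distance_m`, `disk_state`,
#'   `direct_max_db`, `reflected_max_db`, `ici_ms`, `direct_time_ms`,
#'   `reflected_time_ms`.
#' @export
analyze_recording <- function(recording, window_ms = 1, hop_samples = 1L,
                              ...) {
  stopifnot(inherits(recording, "echo_recording"))
  m <- extract_maxima(running_spl(recording, window_ms, hop_samples), ...)
  data.frame(
    distance_m = recording$distance,
    disk_state = recording$disk_state,
    direct_max_db = m$direct_db,
    reflected_max_db = m$reflected_db,
    ici_ms = m$ici_ms,
    direct_time_ms = m$direct_time_ms,
    reflected_time_ms = m$reflected_time_ms,
    stringsAsFactors = FALSE
  )
}

#' Analyze a measurement series
#'
#' Analyzes every recording and averages the derived quantities (dB levels
#' and times) over replicates of the same distance and state. When both
#' states are present at a distance, a reflecting-state measurement is
#' flagged `low_confidence` if its reflected maximum is within 3 dB of the
#' non-reflecting level at the same distance, i.e. barely above the room
#' decay it must be detected against.
#'
#' @param recordings An `echo_recording_set`, a list of `echo_recording`, or
#'   a directory path written by [write_measurement_series()].
#' @param ... Passed to [analyze_recording()].
#' @return Data frame of class `echo_series`, one row per distance and
#'   state, with replicate means, the replicate count `n_rep`, and the
#'   replicate standard deviation `reflected_sd_db`.
#' @export
analyze_series <- function(recordings, ...) {
  if (is.character(recordings)) {
    recordings <- read_measurement_series(recordings)
  }
  stopifnot(length(recordings) >= 1L)
  rows <- do.call(rbind, lapply(recordings, analyze_recording, ...))
  key <- interaction(rows$distance_m, rows$disk_state, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, mean))
  out <- data.frame(
    distance_m = as.numeric(tapply(rows$distance_m, key, mean)),
    disk_state = as.character(tapply(rows$disk_state, key, `[`, 1L)),
    direct_max_db = agg(rows$direct_max_db),
    reflected_max_db = agg(rows$reflected_max_db),
    ici_ms = agg(rows$ici_ms),
    reflected_sd_db = as.numeric(tapply(rows$reflected_max_db, key,
                                        stats::sd)),
    n_rep = as.integer(tapply(rows$reflected_max_db, key, length)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance_m, out$disk_state), ]
  rownames(out) <- NULL
  out$low_confidence <- NA
  refl <- out$disk_state == "reflecting"
  non <- out[out$disk_state == "nonreflecting", ]
  if (nrow(non)) {
    idx <- match(out$distance_m[refl], non$distance_m)
    out$low_confidence[refl] <-
      out$reflected_max_db[refl] < non$reflected_max_db[idx] + 3
  }
  class(out) <- c("echo_series", "data.frame")
  out
}

#' Slope of inter-click interval against distance
#'
#' Ordinary least-squares slope of the ICI (ms) on distance (m) over the
#' reflecting-state rows of a series; geometrically this estimates
#' `2 / sound_speed`.
#'
#' @param series An `echo_series` from [analyze_series()].
#' @param distance_range Two-element range of distances (m) included in the
#'   fit.
#' @return Slope in ms per metre.
#' @export
fit_ici_slope <- function(series, distance_range = c(0.7, 3.9)) {
  s <- series[series$disk_state == "reflecting" &
                series$distance_m >= distance_range[1] &
                series$distance_m <= distance_range[2], ]
  if (length(unique(s$distance_m)) < 3L) {
    stop("need at least 3 distinct distances in range to fit a slope")
  }
  unname(stats::coef(stats::lm(ici_ms ~ distance_m, data = s))[2])
}

#' Reflected-level decay per doubling of distance
#'
#' Least-squares slope of the reflected maximum SPL on log2(distance) over
#' the reflecting-state rows within `distance_range`, returned as a positive
#' decay in dB per doubling.
#'
#' @inheritParams fit_ici_slope
#' @return Decay in dB per doubling of distance (positive for a level that
#'   falls with distance).
#' @export
fit_level_decay <- function(series, distance_range = c(0.7, 2.0)) {
  s <- series[series$disk_state == "reflecting" &
                series$distance_m >= distance_range[1] &
                series$distance_m <= distance_range[2], ]
  if (length(unique(s$distance_m)) < 3L) {
    stop("need at least 3 distinct distances in range to fit a decay")
  }
  s$log2_d <- log2(s$distance_m)
  -unname(stats::coef(stats::lm(reflected_max_db ~ log2_d, data = s))[2])
}

#' Combined level of two incoherent sources
#'
#' Power sum of two dB levels: `10 log10(10^(a/10) + 10^(b/10))`.
#'
#' @param direct_db,reflected_db Levels in dB (vectorised).
#' @return Combined level in dB.
#' @examples
#' combined_level(76, 76)  # +3.01 dB
#' @export
combined_level <- function(direct_db, reflected_db) {
  10 * log10(10^(direct_db / 10) + 10^(reflected_db / 10))
}

#' Summary statistics of a measurement series
#'
#' The headline quantities of the windowed-SPL analysis: the ICI slope, the
#' reflected-level decay per doubling (over its stated validity range), the
#' direct level and its spread across distances, and the reflected level and
#' reflected-to-direct ratio at the farthest distance.
#'
#' @param series An `echo_series`.
#' @param ici_range Distance range for the ICI slope fit.
#' @param decay_range Distance range for the level-decay fit.
#' @return List with `ici_slope_ms_per_m`, `level_decay_db_per_doubling`,
#'   `direct_level_db` (mean), `direct_level_range_db`,
#'   `reflected_at_max_db`, `ratio_at_max_db`, `max_distance_m`.
#' @export
summarize_series <- function(series, ici_range = c(0.7, 3.9),
                             decay_range = c(0.7, 2.0)) {
  refl <- series[series$disk_state == "reflecting", ]
  if (!nrow(refl)) stop("series has no reflecting-state rows")
  far <- refl[which.max(refl$distance_m), ]
  list(
    ici_slope_ms_per_m = fit_ici_slope(series, ici_range),
    level_decay_db_per_doubling = fit_level_decay(series, decay_range),
    direct_level_db = mean(refl$direct_max_db),
    direct_level_range_db = diff(range(refl$direct_max_db)),
    reflected_at_max_db = far$reflected_max_db,
    ratio_at_max_db = far$reflected_max_db - far$direct_max_db,
    max_distance_m = far$distance_m
  )
}

#' Plot an SPL trace
#'
#' @param x An `spl_trace`.
#' @param ... Passed to [plot()].
#' @export
plot.spl_trace <- function(x, ...) {
  plot(x$time_ms, x$spl_db, type = "l", xlab = "Time [ms]",
       ylab = "SPL [dB]", ...)
  invisible(x)
}
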