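#' Mean threshold over sessions
#'
#' @param session_thresholds Non-empty numeric vector of per-session
#'   threshold estimates in metres.
#' @return Arithmetic mean in metres.
#' @export
mean_threshold <- function(session_thresholds) {
  stopifnot(is.numeric(session_thresholds))
  if (length(session_thresholds) == 0L) {
    stop("`session_thresholds` must be non-empty")
  }
  mean(session_thresholds)
}

#' Training-effect rank correlation
#'
#' Spearman's rank-order correlation between session order (1, 2, ...) and
#' the session thresholds, the summary used to quantify improvement across
#' sessions. Ties are handled with average ranks.
#'
#' @inheritParams mean_threshold
#' @return Spearman's rho in \[-1, 1\], or `NA` (with a warning) when the
#'   thresholds are constant and the correlation is undefined.
#' @examples
#' spearman_session_trend(c(1, 2, 3, 5, 4))  # 0.9
#' @export
spearman_session_trend <- function(session_thresholds) {
  stopifnot(is.numeric(session_thresholds))
  if (length(session_thresholds) < 3L) {
    stop("need at least 3 sessions for a rank correlation")
  }
  if (stats::sd(session_thresholds) == 0) {
    warning("constant thresholds: rank correlation is undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(seq_along(session_thresholds), session_thresholds,
             method = "spearman")
}

#' Per-day threshold summaries
#'
#' Splits an ordered vector of session thresholds into consecutive days of
#' `sessions_per_day` sessions each and returns the per-day mean and standard
#' error (sample standard deviation over the square root of the day's session
#' count).
#'
#' @inheritParams mean_threshold
#' @param sessions_per_day Number of sessions per test day; the total session
#'   count must be an exact multiple.
#' @return Data frame with columns `day`, `mean_m`, `se_m`, `n_sessions`.
#' @examples
#' per_day_summary(c(1, 3), sessions_per_day = 2)  # mean 2, SE 1
#' @export
per_day_summary <- function(session_thresholds, sessions_per_day = 12L) {
  stopifnot(is.numeric(session_thresholds), sessions_per_day >= 1L)
  n <- length(session_thresholds)
  if (n == 0L || n %% sessions_per_day != 0L) {
    stop(sprintf(
      "%d sessions cannot be split into whole days of %d sessions",
      n, sessions_per_day))
  }
  day <- rep(seq_len(n %/% sessions_per_day), each = sessions_per_day)
  means <- tapply(session_thresholds, day, mean)
  sds <- tapply(session_thresholds, day, stats::sd)
  data.frame(
    day = as.integer(names(means)),
    mean_m = as.numeric(means),
    se_m = as.numeric(sds) / sqrt(sessions_per_day),
    n_sessions = as.integer(sessions_per_day),
    row.names = NULL
  )
}

#' Participant-level summary
#'
#' Bundles the summaries reported per participant: the mean threshold over
#' all sessions, the session-order rank correlation, and (when
#' `sessions_per_day` is given) per-day means with standard errors.
#'
#' @param session_thresholds Ordered numeric vector of session thresholds.
#' @param participant_id Label for the participant.
#' @param sessions_per_day Optional; if supplied, a per-day summary is
#'   included.
#' @return An object of class `participant_summary`.
#' @export
participant_summary <- function(session_thresholds, participant_id = "P1",
                                sessions_per_day = NULL) {
  out <- list(
    participant_id = as.character(participant_id),
    session_thresholds = session_thresholds,
    mean_threshold = mean_threshold(session_thresholds),
    spearman_rho = spearman_session_trend(session_thresholds),
    per_day = if (!is.null(sessions_per_day)) {
      per_day_summary(session_thresholds, sessions_per_day)
    }
  )
  structure(out, class = "participant_summary")
}

#' @export
print.participant_summary <- function(x, ...) {
  cat(sprintf("%s: mean threshold %.3f m over %d sessions, Spearman rho %+.2f\n",
              x$participant_id, x$mean_threshold,
              length(x$session_thresholds), x$spearman_rho))
  if (!is.null(x$per_day)) {
    print(x$per_day)
  }
  invisible(x)
}

#' Write participant summaries to CSV
#'
#' One row per participant with the numeric summary columns
#' (`participant`, `mean_threshold_m`, `spearman_rho`).
#'
#' @param summaries A `participant_summary` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "participant_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(participant = s$participant_id,
               mean_threshold_m = s$mean_threshold,
               spearman_rho = s$spearman_rho,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
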