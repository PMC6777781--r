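trial_log_columns <- c("session_id", "trial", "distance_m", "disk_state",
                       "response", "outcome", "is_reversal")

#' Write staircase sessions to a trial-log CSV
#'
#' Serialises one or more sessions to the interchange format used between
#' the staircase engine and the session statistics: one row per trial with
#' columns `session_id`, `trial`, `distance_m` (3 decimals), `disk_state`,
#' `response`, `outcome`, `is_reversal`.
#'
#' @param sessions A `siam_session` (from [run_session()]) or a list of them.
#' @param path Output CSV path.
#' @param session_ids Optional character labels, one per session.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(sessions, path, session_ids = NULL) {
  if (inherits(sessions, "siam_session")) sessions <- list(sessions)
  stopifnot(all(vapply(sessions, inherits, logical(1), "siam_session")))
  if (is.null(session_ids)) {
    session_ids <- sprintf("S%02d", seq_along(sessions))
  }
  stopifnot(length(session_ids) == length(sessions))
  df <- do.call(rbind, Map(function(s, id) {
    data.frame(
      session_id = id,
      trial = s$trials$index,
      distance_m = sprintf("%.3f", s$trials$distance),
      disk_state = s$trials$disk_state,
      response = s$trials$response,
      outcome = s$trials$outcome,
      is_reversal = s$trials$is_reversal,
      stringsAsFactors = FALSE
    )
  }, sessions, session_ids))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial-log CSV
#'
#' @param path CSV path written by [write_trial_log()] (or recorded by
#'   compatible experimental software).
#' @return Data frame with the trial-log columns; `distance_m` numeric,
#'   `is_reversal` logical.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_log_columns, names(df))
  if (length(missing)) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$distance_m <- as.numeric(df$distance_m)
  df$is_reversal <- as.logical(df$is_reversal)
  match_enum(df$disk_state, c("reflecting", "nonreflecting"), "disk_state")
  match_enum(df$response, c("yes", "no"), "response")
  df[trial_log_columns]
}

#' Recompute session thresholds from a trial log
#'
#' Replays each logged session through the staircase rules: outcomes are
#' re-derived from reflector state and response, post-step distances are
#' recomputed with [next_distance()], reversals re-flagged with
#' [detect_reversals()], and the threshold taken as the mean of the last
#' `n_reversals_avg` reversal distances. Sessions whose logged trajectory is
#' inconsistent with the staircase rules raise an error.
#'
#' @param log Data frame from [read_trial_log()].
#' @param config The [staircase_config()] the sessions were run with.
#' @return Named numeric vector of thresholds (metres), one per session, in
#'   order of first appearance.
#' @export
session_thresholds_from_log <- function(log, config = staircase_config()) {
  stopifnot(all(trial_log_columns %in% names(log)))
  ids <- unique(log$session_id)
  out <- vapply(ids, function(id) {
    tr <- log[log$session_id == id, ]
    tr <- tr[order(tr$trial), ]
    outcome <- classify_outcome(tr$disk_state, tr$response)
    if (!all(outcome == tr$outcome)) {
      stop(sprintf("session %s: logged outcomes contradict state x response", id))
    }
    post <- vapply(seq_len(nrow(tr)), function(i) {
      next_distance(tr$distance_m[i], outcome[i], config)
    }, numeric(1))
    if (nrow(tr) > 1L &&
        any(abs(post[-nrow(tr)] - tr$distance_m[-1L]) > 1e-9)) {
      stop(sprintf("session %s: logged distances do not follow the step rules", id))
    }
    rev <- detect_reversals(config$steps_m[outcome])
    revs <- post[rev]
    if (length(revs) >= config$n_reversals_avg) {
      threshold_from_reversals(revs, config$n_reversals_avg)
    } else if (length(revs) > 0L) {
      suppressWarnings(
        threshold_from_reversals(revs, config$n_reversals_avg, partial = TRUE))
    } else {
      post[length(post)]
    }
  }, numeric(1))
  names(out) <- ids
  out
}
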