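#' Random responder
#'
#' A response model that answers "yes" with fixed probability `p_yes`,
#' independent of distance and reflector state. Used to calibrate chance-level
#' performance of the staircase.
#'
#' @param p_yes Probability of a "yes" response.
#' @return An object of class `c("random_observer", "echo_observer")`.
#' @seealso [sdt_observer()], [respond()], [calibrate_random_responder()]
#' @export
random_observer <- function(p_yes = 0.5) {
  stopifnot(is.numeric(p_yes), length(p_yes) == 1L, p_yes >= 0, p_yes <= 1)
  structure(list(p_yes = p_yes),
            class = c("random_observer", "echo_observer"))
}

#' Signal-detection-theory observer
#'
#' An equal-variance Gaussian yes--no observer whose sensitivity declines
#' with distance from the reflector. By default sensitivity decays linearly,
#' `d'(d) = max(0, dprime_at_ref - decay_per_m * (d - ref_distance))`; an
#' arbitrary sensitivity profile can be supplied via `dprime_fun`. Response
#' probabilities follow the equal-variance model with criterion `c`:
#' `p(yes | reflecting) = pnorm(d'/2 - c)` and
#' `p(yes | nonreflecting) = pnorm(-d'/2 - c)`.
#'
#' @param dprime_at_ref Sensitivity (d') at `ref_distance`.
#' @param ref_distance Reference distance in metres.
#' @param decay_per_m Linear d' decrease per metre beyond `ref_distance`
#'   (floored at zero).
#' @param criterion Decision criterion c; 0 is unbiased, positive values are
#'   conservative ("yes" less often).
#' @param dprime_fun Optional function `f(distance)` returning d'; overrides
#'   the linear decay.
#' @return An object of class `c("sdt_observer", "echo_observer")`.
#' @examples
#' obs <- sdt_observer(3, ref_distance = 0.7, decay_per_m = 1)
#' dprime_at(obs, 2.7)                     # 1.0
#' yes_prob(obs, 2.7, "reflecting")        # pnorm(0.5)
#' @export
sdt_observer <- function(dprime_at_ref, ref_distance = 0.7, decay_per_m = 0,
                         criterion = 0, dprime_fun = NULL) {
  stopifnot(is.numeric(dprime_at_ref), dprime_at_ref >= 0,
            is.numeric(ref_distance), is.numeric(decay_per_m),
            is.numeric(criterion))
  if (!is.null(dprime_fun)) stopifnot(is.function(dprime_fun))
  structure(
    list(dprime_at_ref = dprime_at_ref, ref_distance = ref_distance,
         decay_per_m = decay_per_m, criterion = criterion,
         dprime_fun = dprime_fun),
    class = c("sdt_observer", "echo_observer")
  )
}

#' Sensitivity of an observer at a distance
#'
#' @param observer An observer model.
#' @param distance Distance in metres (vectorised).
#' @return d' value(s); 0 for a random responder.
#' @export
dprime_at <- function(observer, distance) UseMethod("dprime_at")

#' @export
dprime_at.random_observer <- function(observer, distance) {
  rep(0, length(distance))
}

#' @export
dprime_at.sdt_observer <- function(observer, distance) {
  if (!is.null(observer$dprime_fun)) {
    pmax(0, observer$dprime_fun(distance))
  } else {
    pmax(0, observer$dprime_at_ref -
           observer$decay_per_m * (distance - observer$ref_distance))
  }
}

#' Probability of a "yes" response
#'
#' @inheritParams dprime_at
#' @param disk_state `"reflecting"` or `"nonreflecting"`.
#' @return Probability in \[0, 1\].
#' @export
yes_prob <- function(observer, distance, disk_state) UseMethod("yes_prob")

#' @export
yes_prob.random_observer <- function(observer, distance, disk_state) {
  match_enum(disk_state, c("reflecting", "nonreflecting"), "disk_state")
  rep(observer$p_yes, max(length(distance), length(disk_state)))
}

#' @export
yes_prob.sdt_observer <- function(observer, distance, disk_state) {
  disk_state <- match_enum(disk_state, c("reflecting", "nonreflecting"),
                           "disk_state")
  dp <- dprime_at(observer, distance)
  sgn <- ifelse(disk_state == "reflecting", 1, -1)
  stats::pnorm(sgn * dp / 2 - observer$criterion)
}

#' Draw one response from an observer
#'
#' A single Bernoulli draw from the observer's yes-probability at the given
#' distance and reflector state, using the current R random number stream.
#'
#' @inheritParams yes_prob
#' @return `"yes"` or `"no"`.
#' @export
respond <- function(observer, distance, disk_state) UseMethod("respond")

#' @export
respond.echo_observer <- function(observer, distance, disk_state) {
  if (stats::runif(1) < yes_prob(observer, distance, disk_state)) "yes" else "no"
}

#' Percent correct of an unbiased yes--no observer
#'
#' Under the equal-variance Gaussian model with equal presentation priors and
#' criterion c = 0, both the hit rate and the correct rejection rate equal
#' `pnorm(dprime / 2)`, so that is also the proportion correct.
#'
#' @param dprime Sensitivity d' (non-negative, vectorised).
#' @return Proportion correct in \[0.5, 1\].
#' @examples
#' proportion_correct_unbiased(1)   # 0.6915
#' @export
proportion_correct_unbiased <- function(dprime) {
  stopifnot(is.numeric(dprime))
  if (any(dprime < 0)) stop("`dprime` must be non-negative")
  stats::pnorm(dprime / 2)
}

#' Distance at which an observer's sensitivity crosses a target
#'
#' Solves `dprime_at(observer, d) == target` for `d`. For the default linear
#' profile this is analytic; for a custom `dprime_fun` it is found by root
#' search over `interval`.
#'
#' @param observer An [sdt_observer()].
#' @param target Target d' value.
#' @param interval Search interval in metres (used for custom profiles).
#' @return Crossing distance in metres, or `NA` if sensitivity never crosses
#'   the target.
#' @export
dprime_crossing <- function(observer, target = 1.0, interval = c(0.7, 3.9)) {
  stopifnot(inherits(observer, "sdt_observer"), target > 0)
  if (is.null(observer$dprime_fun)) {
    if (observer$decay_per_m <= 0) {
      return(NA_real_)
    }
    d <- observer$ref_distance +
      (observer$dprime_at_ref - target) / observer$decay_per_m
    return(d)
  }
  f <- function(d) dprime_at(observer, d) - target
  lo <- f(interval[1])
  hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    return(NA_real_)
  }
  stats::uniroot(f, interval)$root
}

#' Drift-zero distance of the SIAM staircase for an observer
#'
#' The staircase's expected per-trial movement at distance d is
#' `p_reflect * (H(d) * s_hit + (1 - H(d)) * s_miss) +
#'  (1 - p_reflect) * (F(d) * s_fa + (1 - F(d)) * s_cr)`,
#' with H and F the observer's hit and false-alarm rates. The staircase
#' equilibrates where this drift is zero; for the default step matrix and
#' `p_reflect = 0.5` that is where `H - F = 0.5`, i.e. d' = 2 * qnorm(0.75)
#' of about 1.35 for an unbiased observer (not d' = 1; see the methods
#' vignette). Reversal-averaged session thresholds concentrate near this
#' distance once the start-up transient has decayed.
#'
#' @param observer An observer model.
#' @param config A [staircase_config()].
#' @return Distance in metres where the expected drift is zero. If the drift
#'   does not change sign inside the rail, the bound towards which the drift
#'   pushes is returned with a warning.
#' @export
siam_target_distance <- function(observer, config = staircase_config()) {
  drift <- function(d) {
    h <- yes_prob(observer, d, "reflecting")
    f <- yes_prob(observer, d, "nonreflecting")
    config$p_reflect *
      (h * config$steps_m[["hit"]] + (1 - h) * config$steps_m[["miss"]]) +
      (1 - config$p_reflect) *
        (f * config$steps_m[["false_alarm"]] +
           (1 - f) * config$steps_m[["correct_rejection"]])
  }
  lo <- drift(config$d_min)
  hi <- drift(config$d_max)
  if (sign(lo) == sign(hi)) {
    warning("staircase drift does not change sign inside the rail bounds")
    return(if (lo > 0) config$d_max else config$d_min)
  }
  stats::uniroot(drift, c(config$d_min, config$d_max), tol = 1e-6)$root
}
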