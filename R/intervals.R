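#' Interval-censored event datasets
#'
#' The common data format for censoring-aware estimation: each row is an
#' event interval `(left, right]` with a positive integer weight. Conventions:
#' `left == right` encodes an exactly observed event time (as assumed by
#' right-censored analyses); `right = Inf` encodes right censoring (the
#' animal was last seen alive at `left`); `left = -Inf` (or 0 for
#' current-status data) encodes an event known only to have happened by
#' `right`. Current-status data — each animal inspected once — is the special
#' case where every row is `(0, t]` or `(t, Inf)`.
#'
#' @param left,right Interval edges in days; `left <= right`.
#' @param weight Positive counts per interval (recycled).
#' @return A data.frame of class `"interval_data"` with columns `left`,
#'   `right`, `weight`; identical intervals are aggregated.
#' @examples
#' interval_data(left = c(0, 10), right = c(10, Inf), weight = c(2, 3))
#' @export
interval_data <- function(left, right, weight = 1) {
  if (length(left) != length(right) || length(left) < 1L) {
    stop("`left` and `right` must have equal positive length", call. = FALSE)
  }
  weight <- rep_len(weight, length(left))
  if (any(is.na(left)) || any(is.na(right)) || any(left > right)) {
    stop("intervals require `left <= right` with no missing edges",
         call. = FALSE)
  }
  if (any(is.infinite(left) & left > 0) || any(is.infinite(right) & right < 0)) {
    stop("`left` may be -Inf and `right` may be Inf, not the reverse",
         call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be positive", call. = FALSE)
  }
  if (any(left == right & !is.finite(left))) {
    stop("degenerate intervals must be at finite times", call. = FALSE)
  }
  out <- stats::aggregate(weight ~ left + right,
                          data = data.frame(left = left, right = right,
                                            weight = weight),
                          FUN = sum)
  out <- out[order(out$right, out$left), c("left", "right", "weight")]
  rownames(out) <- NULL
  class(out) <- c("interval_data", "data.frame")
  out
}

#' @export
print.interval_data <- function(x, ...) {
  cat(sprintf("interval-censored dataset: %d distinct intervals, %g events\n",
              nrow(x), sum(x$weight)))
  NextMethod()
}

#' Convert a TLM trial to event intervals
#'
#' With `mode = "interval"` each recorded death at observation time `t`
#' becomes the interval `(t - interval, t]` (the death happened at an unknown
#' time since the previous scheduled observation; deaths at the day-0
#' baseline, possible only through mis-scoring, become `(-Inf, 0]`). With
#' `mode = "right"` the death is taken at face value as an exact event at
#' `t`, the assumption made by right-censored Kaplan-Meier analysis. Animals
#' left unscored by the safety cap contribute right-censored intervals.
#'
#' @param trial A [run_tlm_trial()] result.
#' @param mode `"interval"` or `"right"`.
#' @return An [interval_data()] object.
#' @export
tlm_to_intervals <- function(trial, mode = c("interval", "right")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trial, "tlm_trial"))
  rec <- trial$recorded_death_times
  dead <- !is.na(rec)
  if (!any(dead)) stop("trial contains no recorded deaths", call. = FALSE)
  rec <- rec[dead]
  if (mode == "right") {
    left <- rec
  } else {
    left <- rec - trial$interval
    left[rec == 0] <- -Inf
  }
  right <- rec
  if (any(!dead)) { # safety-cap truncation: still on plate at the last time
    t_last <- max(trial$observations$time)
    left <- c(left, t_last)
    right <- c(right, Inf)
  }
  interval_data(left, right)
}

#' Convert an RSM trial to current-status intervals
#'
#' Each animal scored dead at plate time `t` contributes `(0, t]`; each
#' animal scored alive contributes `(t, Inf)`. Only the current status at a
#' single inspection time is ever known for an animal.
#'
#' @param trial A [run_rsm_trial()] result.
#' @return An [interval_data()] object.
#' @export
rsm_to_intervals <- function(trial) {
  stopifnot(inherits(trial, "rsm_trial"))
  obs <- trial$observations
  if (nrow(obs) < 1L) stop("trial has no observations", call. = FALSE)
  left <- c(rep(0, nrow(obs)), obs$time)
  right <- c(obs$time, rep(Inf, nrow(obs)))
  w <- c(obs$n_dead, obs$n_live)
  keep <- w > 0
  interval_data(left[keep], right[keep], w[keep])
}
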