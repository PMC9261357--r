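#' Scoring-error models
#'
#' Describes how experimenter error enters a simulated trial. Two effects are
#' distinguished and never combined within one trial:
#'
#' * `"misscore"`: at an observation, the recorded status of an animal is the
#'   opposite of its true status with probability `P(t)` (a live animal is
#'   called dead, or a dead animal called alive).
#' * `"hazard"`: rough handling at an observation kills a truly live animal
#'   with probability `P(t)`; it is recorded dead at that observation. Dead
#'   animals are always scored correctly.
#'
#' The probability `P(t)` is either zero (`"none"`), constant at `max_p`
#' (`"constant"`), or rises from zero to `max_p` following the logistic CDF
#' `F` with parameters `(curve_mu, curve_s)` — by default those of the
#' reference generating distribution — mirroring the loss of mobility and
#' onset of paralysis in aging animals. `"late_onset"` uses
#' `P(t) = max_p * F(t)`, so the error rate tracks the decline in survival
#' itself; `"mid_onset"` uses `P(t) = max_p * F(1.5 t)`, shifting the rise of
#' the curve earlier into mid-life.
#'
#' @param kind One of `"none"`, `"constant"`, `"late_onset"`, `"mid_onset"`.
#' @param effect `"misscore"` or `"hazard"`.
#' @param max_p Maximum (or constant) error probability in `[0, 1]`.
#' @param curve_mu,curve_s Logistic parameters (days) of the error-rate curve
#'   for the time-dependent kinds.
#' @return An object of class `"error_model"`.
#' @examples
#' error_model("constant", max_p = 0.02)
#' error_model("mid_onset", max_p = 0.1, effect = "hazard")
#' @export
error_model <- function(kind = c("none", "constant", "late_onset", "mid_onset"),
                        effect = c("misscore", "hazard"),
                        max_p = 0, curve_mu = 20, curve_s = 2) {
  kind <- match.arg(kind)
  effect <- match.arg(effect)
  if (!is.numeric(max_p) || length(max_p) != 1L || !is.finite(max_p) ||
      max_p < 0 || max_p > 1) {
    stop("`max_p` must lie in [0, 1]", call. = FALSE)
  }
  if (kind %in% c("late_onset", "mid_onset")) check_logistic_params(curve_mu, curve_s)
  if (kind != "none" && max_p == 0) kind <- "none"
  structure(list(kind = kind, effect = effect, max_p = max_p,
                 curve_mu = curve_mu, curve_s = curve_s),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  if (x$kind == "none") {
    cat("error model: none\n")
  } else {
    cat(sprintf("error model: %s %s, max_p = %g", x$kind, x$effect, x$max_p))
    if (x$kind %in% c("late_onset", "mid_onset")) {
      cat(sprintf(" (curve mu = %g d, s = %g d)", x$curve_mu, x$curve_s))
    }
    cat("\n")
  }
  invisible(x)
}

#' Error probability at a given time
#'
#' Evaluates the error-rate curve of an [error_model()] at observation times
#' `t`. Monotone non-decreasing in `t` for the time-dependent kinds and
#' essentially zero at `t = 0` ("the error rate starts at zero").
#'
#' @param t Observation times in days (vectorised), non-negative.
#' @param model An [error_model()].
#' @return Probabilities in `[0, max_p]`.
#' @examples
#' error_probability(20, error_model("late_onset", max_p = 0.04)) # 0.02
#' @export
error_probability <- function(t, model) {
  stopifnot(inherits(model, "error_model"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  switch(model$kind,
    none = rep(0, length(t)),
    constant = rep(model$max_p, length(t)),
    late_onset = model$max_p *
      stats::plogis(t, model$curve_mu, model$curve_s),
    mid_onset = model$max_p *
      stats::plogis(1.5 * t, model$curve_mu, model$curve_s))
}
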