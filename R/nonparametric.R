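# Non-parametric survival curve estimation: Kaplan-Meier for exact /
# right-censored data, Turnbull NPMLE for general interval censoring.

new_survival_curve <- function(time, survival, estimator, n) {
  structure(list(time = time, survival = survival, estimator = estimator,
                 n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  s <- curve_summaries(x)
  cat(sprintf(
    "survival curve (%s), %g events: median %.3g, mean %.3g, q95 %.3g\n",
    x$estimator, x$n, s$median, s$mean, s$q95))
  invisible(x)
}

#' Kaplan-Meier estimate for exact and right-censored data
#'
#' Product-limit estimator via [survival::survfit()]. Accepts only datasets
#' whose rows are exact event times (`left == right`) or right-censored
#' records (`right = Inf`): genuinely interval-censored data — including the
#' current-status data produced by replica set experiments, where no exact
#' death time is ever observed — is refused; use [npmle_interval()] for
#' those.
#'
#' @param data An [interval_data()] object.
#' @return A `"survival_curve"` (times and survival probabilities, stepped).
#' @examples
#' km_right_censored(interval_data(1:4, 1:4))
#' @export
km_right_censored <- function(data) {
  data <- as_interval_data(data)
  exact <- data$left == data$right
  rc <- is.infinite(data$right)
  if (!all(exact | rc)) {
    stop("dataset contains true event intervals (left < right < Inf); ",
         "right-censored Kaplan-Meier cannot represent them (for ",
         "current-status RSM data use npmle_interval())", call. = FALSE)
  }
  if (!any(exact)) stop("no events to estimate from", call. = FALSE)
  time <- ifelse(exact, data$right, data$left)
  fit <- survival::survfit(
    survival::Surv(time, as.numeric(exact)) ~ 1,
    weights = data$weight)
  keep <- fit$n.event > 0
  new_survival_curve(fit$time[keep], fit$surv[keep], "km_right",
                     sum(data$weight[exact]))
}

#' Turnbull NPMLE for interval-censored data
#'
#' Non-parametric maximum likelihood estimate of the survival function for
#' arbitrarily interval-censored data (the self-consistency/EM estimate over
#' the Turnbull equivalence classes), computed by [survival::survfit()] on an
#' `"interval2"` response. Probability mass inside a Turnbull interval is
#' located at its midpoint for point summaries, the convention used
#' throughout for interval-censored curves. On degenerate data (all exact
#' event times) the estimate reduces to Kaplan-Meier.
#'
#' @param data An [interval_data()] object.
#' @return A `"survival_curve"` with times at Turnbull-interval midpoints.
#' @examples
#' npmle_interval(interval_data(c(0, 10), c(10, Inf), weight = c(5, 5)))
#' @export
npmle_interval <- function(data) {
  data <- as_interval_data(data)
  t1 <- ifelse(is.finite(data$left), data$left, NA_real_)
  t2 <- ifelse(is.finite(data$right), data$right, NA_real_)
  # interval2 coding: (NA, t] left-censored, [t, NA) right-censored,
  # t1 == t2 exact; open interval events get t1 < t2.
  fit <- survival::survfit(
    survival::Surv(t1, t2, type = "interval2") ~ 1,
    weights = data$weight)
  surv <- fit$surv
  time <- fit$time
  keep <- is.finite(time) & is.finite(surv)
  # drop zero-mass support points, keep the stepped mass locations
  prev <- c(1, surv[keep][-sum(keep)])
  mass <- prev - surv[keep]
  sel <- mass > 1e-10
  new_survival_curve(time[keep][sel], surv[keep][sel], "npmle_interval",
                     sum(data$weight))
}

#' Point summaries of an estimated survival curve
#'
#' The median is the smallest curve time at which survival falls to 0.5 or
#' below (ties broken toward the earlier time), and the 95% quantile
#' lifespan `q95` the smallest time with survival at or below 0.05. The mean
#' is the restricted mean survival time: the area under the stepped curve up
#' to its last mass point. With no censoring these equal the sample median
#' and mean of the event times; for interval-censored curves the mass
#' locations are Turnbull-interval midpoints.
#'
#' @param curve A `"survival_curve"` from [km_right_censored()] or
#'   [npmle_interval()].
#' @return A list with `median`, `mean` and `q95` (days); `median`/`q95` are
#'   `NA` with a warning when the curve never reaches the probability.
#' @export
curve_summaries <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  time <- curve$time
  surv <- curve$survival
  qtl <- function(p) {
    hit <- which(surv <= p + 1e-12)
    if (!length(hit)) {
      warning(sprintf("survival curve never reaches %g; quantile undefined", p),
              call. = FALSE)
      return(NA_real_)
    }
    time[hit[1]]
  }
  # area under the step function on [0, last mass point]
  prev_surv <- c(1, surv[-length(surv)])
  prev_time <- c(0, time[-length(time)])
  rmean <- sum(prev_surv * (time - prev_time))
  list(median = qtl(0.5), mean = rmean, q95 = qtl(0.05))
}
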