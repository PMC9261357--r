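# Accuracy/precision summaries across trial sets, and effort accounting.

#' Standard error of a set of estimates
#'
#' Sample standard deviation divided by the square root of the number of
#' estimates: the precision metric reported across simulated trial sets.
#'
#' @param estimates Numeric vector (length at least 2).
#' @return Standard error, same units as the estimates.
#' @examples
#' se_of_estimates(c(19, 20, 21)) # 1/sqrt(3)
#' @export
se_of_estimates <- function(estimates) {
  if (length(estimates) < 2L || any(is.na(estimates))) {
    stop("need at least two non-missing estimates", call. = FALSE)
  }
  stats::sd(estimates) / sqrt(length(estimates))
}

#' Mean squared error of a set of estimates
#'
#' Mean of squared deviations from the known true value: the accuracy metric
#' for simulated trials, decomposable as variance + bias^2.
#'
#' @param estimates Numeric vector.
#' @param true_value The generating-distribution value being estimated.
#' @return MSE in squared units.
#' @examples
#' mse_of_estimates(c(19, 21), 20) # 1
#' @export
mse_of_estimates <- function(estimates, true_value) {
  if (!length(estimates) || any(is.na(estimates))) {
    stop("need at least one non-missing estimate", call. = FALSE)
  }
  mean((estimates - true_value)^2)
}

#' Total animal observations in a trial
#'
#' The effort proxy: the number of times any animal is assessed during the
#' trial, counting live and dead animals and, for TLM, animals re-assessed
#' at successive observations (the sum over observations of the animals
#' still on the plate, including the day-0 baseline count). For RSM it is
#' the number of plates scored times the animals per plate.
#'
#' @param trial A `tlm_trial` or `rsm_trial`.
#' @return Integer count.
#' @export
count_observations <- function(trial) {
  if (inherits(trial, "tlm_trial")) {
    sum(trial$observations$n_live + trial$observations$n_dead)
  } else if (inherits(trial, "rsm_trial")) {
    trial$n_per_plate * nrow(trial$observations)
  } else {
    stop("`trial` must be a tlm_trial or rsm_trial", call. = FALSE)
  }
}

#' Fit every trial of a set and collect lifespan estimates
#'
#' Applies one analysis treatment to each simulated trial: `"logistic"`
#' (parametric interval MLE, the RSM-style analysis, also applicable to TLM
#' interval data), `"km_right"` (right-censored Kaplan-Meier; TLM only — the
#' estimator cannot represent current-status data), or `"npmle_interval"`
#' (Turnbull NPMLE on interval-censored data).
#'
#' @param trials List of trials from [run_trial_set()].
#' @param analysis Analysis treatment.
#' @return A data.frame with one row per trial: `median`, `mean`, `q95`
#'   (days), `converged`, and `total_observations`.
#' @export
fit_trials <- function(trials,
                       analysis = c("logistic", "km_right", "npmle_interval")) {
  analysis <- match.arg(analysis)
  rows <- lapply(seq_along(trials), function(i) {
    trial <- trials[[i]]
    dat <- if (inherits(trial, "rsm_trial")) {
      if (analysis == "km_right") {
        stop("right-censored Kaplan-Meier cannot analyze RSM current-status ",
             "data; use analysis = \"logistic\" or \"npmle_interval\"",
             call. = FALSE)
      }
      rsm_to_intervals(trial)
    } else {
      tlm_to_intervals(trial, if (analysis == "km_right") "right" else "interval")
    }
    if (analysis == "logistic") {
      f <- fit_logistic_mle(dat)
      data.frame(trial = i, median = f$median, mean = f$mean, q95 = f$q95,
                 converged = f$converged,
                 total_observations = count_observations(trial))
    } else {
      curve <- if (analysis == "km_right") km_right_censored(dat) else
        npmle_interval(dat)
      s <- curve_summaries(curve)
      data.frame(trial = i, median = s$median, mean = s$mean, q95 = s$q95,
                 converged = TRUE,
                 total_observations = count_observations(trial))
    }
  })
  do.call(rbind, rows)
}

#' Summarize accuracy and precision across a trial set
#'
#' Location across trials is the median of the per-trial median lifespans;
#' precision is their standard error (with the standard deviation also
#' reported, so runs with different trial counts can be compared) and
#' accuracy their mean squared error about the true generating median.
#'
#' @param estimates A data.frame from [fit_trials()].
#' @param true_median Generating-distribution median, days.
#' @return A one-row data.frame: `n_trials`, `median_of_medians`,
#'   `mean_of_medians`, `sd_median`, `se_median`, `mse_median`,
#'   `total_observations_median` (`NA` when the estimates carry no
#'   observation counts, e.g. when refit from a serialized table).
#' @export
summarize_trial_set <- function(estimates, true_median) {
  m <- estimates$median[estimates$converged]
  tot <- if (is.null(estimates$total_observations)) NA_real_ else
    stats::median(estimates$total_observations)
  data.frame(
    n_trials = nrow(estimates),
    median_of_medians = stats::median(m),
    mean_of_medians = mean(m),
    sd_median = stats::sd(m),
    se_median = se_of_estimates(m),
    mse_median = mse_of_estimates(m, true_median),
    total_observations_median = tot)
}
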