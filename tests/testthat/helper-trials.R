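# Hand-built trial objects for conversion and accounting tests, and a few
# shared reference quantities.

ref_dist <- function() logistic_dist(20, 2)

make_tlm_trial <- function(recorded, interval = 1, n_censored_last = 0) {
  times <- seq(0, max(recorded), by = interval)
  n <- length(recorded)
  n_dead <- vapply(times, function(t) sum(recorded == t), integer(1))
  on_plate <- n - cumsum(n_dead)
  structure(list(
    n_start = n, interval = interval,
    true_death_times = recorded - interval / 2,
    recorded_death_times = recorded,
    observations = data.frame(time = times, n_live = on_plate,
                              n_dead = n_dead,
                              n_censored = rep(0L, length(times))),
    truncated = FALSE, error = error_model("none")),
    class = "tlm_trial")
}

make_rsm_trial <- function(times, n_live, n_dead, n_per_plate = NULL) {
  if (is.null(n_per_plate)) n_per_plate <- n_live[1] + n_dead[1]
  structure(list(
    n_per_plate = n_per_plate, interval = diff(c(0, times))[1],
    n_plates_prepared = length(times),
    true_death_times = NULL,
    observations = data.frame(time = times, n_live = n_live, n_dead = n_dead,
                              n_censored = rep(0L, length(times))),
    terminated_early = FALSE, error = error_model("none")),
    class = "rsm_trial")
}

# median lifespans from a list of trials under the parametric analysis
fitted_medians <- function(trials) {
  est <- fit_trials(trials, "logistic")
  est$median[est$converged]
}
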