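#' Simulate a traditional longitudinal (TLM) lifespan trial
#'
#' One cohort of `n_animals` is placed on a single plate and scored at
#' `t = 0, interval, 2*interval, ...` (the day-0 observation is the baseline
#' count of the freshly set-up population). At every observation each animal
#' still on the plate is assessed; animals scored dead are removed and never
#' re-assessed, while dead animals mis-scored as alive stay on the plate and
#' are re-assessed, with a fresh error draw, at the next observation. The
#' trial ends when the plate is empty.
#'
#' Every animal-observation consumes exactly one uniform draw for the error
#' decision regardless of the error probability, so runs with and without
#' error that share a seed also share death times.
#'
#' @param n_animals Starting cohort size.
#' @param dist Generating distribution ([logistic_dist()] and friends).
#' @param interval Scoring interval in days.
#' @param error An [error_model()].
#' @return An object of class `"tlm_trial"`: a list with `n_start`,
#'   `interval`, `true_death_times`, `recorded_death_times` (`NA` for animals
#'   still on the plate if the safety cap was hit), `observations` (a
#'   data.frame of `time`, `n_live`, `n_dead`, `n_censored`) and `truncated`.
#' @examples
#' set.seed(1)
#' trial <- run_tlm_trial(20, logistic_dist(20, 2))
#' head(trial$observations)
#' @export
run_tlm_trial <- function(n_animals, dist = logistic_dist(), interval = 1,
                          error = error_model("none")) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 1) {
    stop("`n_animals` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("`interval` must be a positive number of days", call. = FALSE)
  }
  stopifnot(inherits(error, "error_model"))
  n_animals <- as.integer(n_animals)

  x <- sample_death_times(n_animals, dist)
  # safety cap against non-terminating configurations (extreme mis-scoring)
  max_obs <- ceiling(10 * max_lifespan(dist) / interval) + 1L

  recorded <- rep(NA_real_, n_animals)
  on_plate <- rep(TRUE, n_animals)
  misscore <- error$effect == "misscore"
  obs_time <- numeric(max_obs)
  obs_live <- integer(max_obs)
  obs_dead <- integer(max_obs)
  k <- 0L
  t <- -interval
  while (any(on_plate) && k < max_obs) {
    k <- k + 1L
    t <- t + interval
    idx <- which(on_plate)
    u <- stats::runif(length(idx))
    alive <- x[idx] > t
    err <- u < error_probability(t, error)
    scored_dead <- if (misscore) {
      (alive & err) | (!alive & !err)
    } else {
      !alive | err # hazard: handling kills a truly live animal
    }
    recorded[idx[scored_dead]] <- t
    on_plate[idx[scored_dead]] <- FALSE
    obs_time[k] <- t
    obs_dead[k] <- sum(scored_dead)
    obs_live[k] <- length(idx) - obs_dead[k]
  }
  truncated <- any(on_plate)
  obs <- data.frame(time = obs_time[seq_len(k)], n_live = obs_live[seq_len(k)],
                    n_dead = obs_dead[seq_len(k)],
                    n_censored = integer(k))
  if (truncated) obs$n_censored[k] <- sum(on_plate)
  structure(list(n_start = n_animals, interval = interval,
                 true_death_times = x, recorded_death_times = recorded,
                 observations = obs, truncated = truncated,
                 error = error),
            class = "tlm_trial")
}

#' Simulate a replica set (RSM) lifespan trial
#'
#' A large synchronized population is split into replicate plates of
#' `n_per_plate` animals; plate `k` is scored once, at `t = k * interval`,
#' and then discarded, so each animal is observed exactly once and only its
#' current status (alive/dead) is known. Enough plates are prepared to reach
#' two observations past the expected maximum lifespan of the generating
#' distribution (its 99% mortality time). The recorded experiment ends two
#' observations after the last observation with any live animal — the
#' standard "two consecutive empty observations" stopping rule — or when the
#' prepared plates are exhausted; note that under mis-scoring a dead animal
#' called alive late in the trial extends the record ("resets the clock").
#'
#' @inheritParams run_tlm_trial
#' @param n_per_plate Animals on each replicate plate.
#' @return An object of class `"rsm_trial"`: a list with `n_per_plate`,
#'   `interval`, `n_plates_prepared`, `true_death_times` (an
#'   `n_per_plate x n_plates_prepared` matrix, one column per plate),
#'   `observations` (one row per scored plate) and `terminated_early`.
#' @examples
#' set.seed(1)
#' trial <- run_rsm_trial(20, logistic_dist(20, 2))
#' tail(trial$observations)
#' @export
run_rsm_trial <- function(n_per_plate, dist = logistic_dist(), interval = 1,
                          error = error_model("none")) {
  if (!is.numeric(n_per_plate) || length(n_per_plate) != 1L || n_per_plate < 1) {
    stop("`n_per_plate` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("`interval` must be a positive number of days", call. = FALSE)
  }
  stopifnot(inherits(error, "error_model"))
  n <- as.integer(n_per_plate)

  n_plates <- as.integer(ceiling(max_lifespan(dist) / interval)) + 2L
  times <- interval * seq_len(n_plates)
  x <- matrix(sample_death_times(n * n_plates, dist), nrow = n)
  u <- matrix(stats::runif(n * n_plates), nrow = n)

  dead_true <- sweep(x, 2, times, `<=`)
  err <- sweep(u, 2, error_probability(times, error), `<`)
  scored_dead <- if (error$effect == "misscore") {
    xor(dead_true, err)
  } else {
    dead_true | (!dead_true & err)
  }
  n_dead <- colSums(scored_dead)
  n_live <- n - n_dead

  last_live <- if (any(n_live > 0)) max(which(n_live > 0)) else 0L
  n_scored <- min(n_plates, last_live + 2L)
  kk <- seq_len(n_scored)
  obs <- data.frame(time = times[kk], n_live = n_live[kk], n_dead = n_dead[kk],
                    n_censored = integer(n_scored))
  structure(list(n_per_plate = n, interval = interval,
                 n_plates_prepared = n_plates, true_death_times = x,
                 observations = obs,
                 terminated_early = n_scored < n_plates,
                 error = error),
            class = "rsm_trial")
}

#' @export
print.tlm_trial <- function(x, ...) {
  cat(sprintf(
    "TLM trial: %d animals, %g-day scoring, %d observations%s\n",
    x$n_start, x$interval, nrow(x$observations),
    if (x$truncated) " (truncated at safety cap)" else ""))
  invisible(x)
}

#' @export
print.rsm_trial <- function(x, ...) {
  cat(sprintf(
    "RSM trial: %d animals/plate, %g-day scoring, %d/%d plates scored%s\n",
    x$n_per_plate, x$interval, nrow(x$observations), x$n_plates_prepared,
    if (x$terminated_early) " (two consecutive empty observations)" else ""))
  invisible(x)
}

#' Reproducible sets of simulated trials
#'
#' Runs `n_trials` independent trials of one configuration, each on its own
#' random number substream derived from `master_seed` with the L'Ecuyer-CMRG
#' generator, so results are bit-reproducible and independent of execution
#' order or parallel scheduling. The caller's random number generator state is
#' left untouched.
#'
#' @param n_trials Number of trials.
#' @param master_seed Integer seed from which per-trial substreams are spawned.
#' @param design `"TLM"` or `"RSM"`.
#' @param n Sample size: animals per trial (TLM) or per observation (RSM).
#' @inheritParams run_tlm_trial
#' @return A list of `n_trials` trial objects, with the per-trial substream
#'   seeds attached as attribute `"seeds"`.
#' @examples
#' trials <- run_trial_set(3, master_seed = 42, design = "RSM", n = 10)
#' length(trials)
#' @export
run_trial_set <- function(n_trials, master_seed, design = c("TLM", "RSM"), n,
                          dist = logistic_dist(), interval = 1,
                          error = error_model("none")) {
  design <- match.arg(design)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be a positive count", call. = FALSE)
  }
  seeds <- trial_seeds(master_seed, n_trials)
  runner <- if (design == "TLM") {
    function() run_tlm_trial(n, dist, interval, error)
  } else {
    function() run_rsm_trial(n, dist, interval, error)
  }
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    assign(".Random.seed", seeds[[i]], envir = globalenv())
    out[[i]] <- runner()
  }
  attr(out, "seeds") <- seeds
  attr(out, "design") <- design
  out
}

#' Per-trial random number substreams
#'
#' Derives `n` independent L'Ecuyer-CMRG substream seeds from one master
#' seed by repeated application of [parallel::nextRNGStream()].
#'
#' @param master_seed Integer master seed.
#' @param n Number of substreams.
#' @return A list of `n` `.Random.seed` vectors.
#' @keywords internal
#' @export
trial_seeds <- function(master_seed, n) {
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      !is.finite(master_seed)) {
    stop("`master_seed` must be a single integer", call. = FALSE)
  }
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
    RNGkind("default")
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
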