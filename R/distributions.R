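#' Logistic survival function
#'
#' Survival probability of the logistic lifespan model,
#' \eqn{S(t) = 1 / (1 + e^{(t - \mu)/s})}. The location \eqn{\mu} is both the
#' mean and the median; \eqn{s > 0} controls the slope of the survival curve
#' around it.
#'
#' @param t Time in days (vectorised). May be `-Inf`/`Inf`.
#' @param mu Location parameter, days.
#' @param s Scale parameter, days; must be positive.
#' @return Survival probabilities in `[0, 1]`, decreasing in `t`.
#' @examples
#' logistic_survival(20, mu = 20, s = 2) # 0.5
#' @export
logistic_survival <- function(t, mu, s) {
  check_logistic_params(mu, s)
  stats::plogis(t, location = mu, scale = s, lower.tail = FALSE)
}

#' Logistic quantile function
#'
#' Inverse of the logistic survival curve. With `type = "survival"` (the
#' default) the argument is a survival probability and
#' \eqn{T(p) = s \ln(1/p - 1) + \mu}, so `T` decreases in `p`; with
#' `type = "cdf"` the argument is a cumulative death fraction and
#' \eqn{T(q) = \mu + s \ln(q/(1-q))}.
#'
#' @param p Probability in (0, 1) (vectorised).
#' @param mu,s Logistic parameters (see [logistic_survival()]).
#' @param type Whether `p` is a survival probability or a death (CDF) fraction.
#' @return Time in days.
#' @examples
#' logistic_quantile(0.5, 20, 2)              # 20
#' logistic_quantile(0.01, 20, 2)             # 20 + 2*log(99)
#' logistic_quantile(0.99, 20, 2, type = "cdf") # same time, CDF convention
#' @export
logistic_quantile <- function(p, mu, s, type = c("survival", "cdf")) {
  type <- match.arg(type)
  check_logistic_params(mu, s)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (type == "survival") s * log(1 / p - 1) + mu else mu + s * log(p / (1 - p))
}

#' Gompertz quantile and distribution functions
#'
#' Two-parameter Gompertz mortality model with baseline rate `alpha` (1/day)
#' and rate of aging `beta` (1/day):
#' \eqn{F(t) = 1 - \exp((\alpha/\beta)(1 - e^{\beta t}))} and quantile
#' \eqn{T(p) = \ln(1 - (\beta/\alpha)\ln(1 - p))/\beta} for a cumulative death
#' fraction `p`.
#'
#' @param p Cumulative death fraction in (0, 1) (vectorised).
#' @param t Time in days (vectorised), non-negative.
#' @param alpha Baseline mortality rate, 1/day; positive.
#' @param beta Rate of aging, 1/day; positive.
#' @return `gompertz_quantile`: time in days; `gompertz_cdf`: death fraction.
#' @examples
#' gompertz_quantile(0.5, alpha = 0.0003271342, beta = 0.3271342007) # 20 days
#' @export
gompertz_quantile <- function(p, alpha, beta) {
  check_gompertz_params(alpha, beta)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  log(1 - (beta / alpha) * log(1 - p)) / beta
}

#' @rdname gompertz_quantile
#' @export
gompertz_cdf <- function(t, alpha, beta) {
  check_gompertz_params(alpha, beta)
  1 - exp((alpha / beta) * (1 - exp(beta * t)))
}

check_logistic_params <- function(mu, s) {
  if (!is.numeric(mu) || !is.numeric(s) || length(mu) != 1L || length(s) != 1L ||
      !is.finite(mu) || !is.finite(s) || s <= 0) {
    stop("logistic parameters require finite `mu` and `s` > 0", call. = FALSE)
  }
  invisible(TRUE)
}

check_gompertz_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || !is.finite(alpha) || !is.finite(beta) ||
      alpha <= 0 || beta <= 0) {
    stop("Gompertz parameters require `alpha` > 0 and `beta` > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Lifespan generating distributions
#'
#' Constructors for the parametric models used to generate simulated animals:
#' logistic (the reference wild-type model), Gompertz (used to probe
#' distribution mismatch), and finite mixtures of either (used to model
#' contaminated populations). All are objects of class `"lifespan_dist"`
#' accepted by [sample_death_times()], [run_tlm_trial()] and
#' [run_rsm_trial()].
#'
#' @param mu,s Logistic location and scale, days.
#' @param alpha,beta Gompertz baseline rate and rate of aging, 1/day.
#' @param weights Non-negative component weights; normalised to sum to 1.
#' @param components List of `lifespan_dist` objects (non-mixture).
#' @return A `lifespan_dist` object.
#' @examples
#' logistic_dist(20, 2)
#' gompertz_dist(0.0003271342, 0.3271342007)
#' @export
logistic_dist <- function(mu = 20, s = 2) {
  check_logistic_params(mu, s)
  structure(list(family = "logistic", mu = mu, s = s), class = "lifespan_dist")
}

#' @rdname logistic_dist
#' @export
gompertz_dist <- function(alpha, beta) {
  check_gompertz_params(alpha, beta)
  structure(list(family = "gompertz", alpha = alpha, beta = beta),
            class = "lifespan_dist")
}

#' @rdname logistic_dist
#' @export
mixture_dist <- function(weights, components) {
  if (length(weights) != length(components) || length(weights) < 1L) {
    stop("`weights` and `components` must have equal positive length",
         call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative and not all zero", call. = FALSE)
  }
  ok <- vapply(components, function(d) {
    inherits(d, "lifespan_dist") && d$family != "mixture"
  }, logical(1))
  if (!all(ok)) {
    stop("each component must be a non-mixture `lifespan_dist`", call. = FALSE)
  }
  structure(list(family = "mixture", weights = weights / sum(weights),
                 components = components), class = "lifespan_dist")
}

#' Two-component contaminated population
#'
#' Convenience wrapper describing a population in which a fraction `frac_a`
#' of animals comes from `dist_a` and the remainder from `dist_b`, e.g. a
#' strain contamination in which 67% of animals have median lifespan 20 days
#' and 33% have 16 days.
#'
#' @param frac_a Fraction of animals from `dist_a`, strictly inside (0, 1).
#' @param dist_a,dist_b Component distributions ([logistic_dist()] etc.).
#' @return A mixture `lifespan_dist`.
#' @examples
#' make_mixture(0.67, logistic_dist(20, 2), logistic_dist(16, 1.6))
#' @export
make_mixture <- function(frac_a, dist_a, dist_b) {
  if (!is.numeric(frac_a) || length(frac_a) != 1L || !is.finite(frac_a) ||
      frac_a <= 0 || frac_a >= 1) {
    stop("`frac_a` must lie strictly inside (0, 1)", call. = FALSE)
  }
  mixture_dist(c(frac_a, 1 - frac_a), list(dist_a, dist_b))
}

#' @export
print.lifespan_dist <- function(x, ...) {
  switch(x$family,
    logistic = cat(sprintf("logistic lifespan distribution: mu = %g d, s = %g d\n",
                           x$mu, x$s)),
    gompertz = cat(sprintf(
      "Gompertz lifespan distribution: alpha = %g /d, beta = %g /d (median %.2f d)\n",
      x$alpha, x$beta, gompertz_quantile(0.5, x$alpha, x$beta))),
    mixture = {
      cat("mixture lifespan distribution:\n")
      for (i in seq_along(x$weights)) {
        cat(sprintf("  %5.1f%% ", 100 * x$weights[i]))
        print(x$components[[i]])
      }
    })
  invisible(x)
}

#' Survival, CDF and quantiles of a generating distribution
#'
#' `dist_survival()` and `dist_cdf()` evaluate the survival function and
#' cumulative death fraction of any `lifespan_dist`; `dist_quantile()`
#' inverts the CDF (numerically, by bisection, for mixtures);
#' `max_lifespan()` returns the expected maximum lifespan, defined as the
#' time by which a fraction `p` of the population has died (99% by default).
#'
#' @param dist A [logistic_dist()], [gompertz_dist()] or [mixture_dist()].
#' @param t Time in days (vectorised).
#' @param p Probability (vectorised for `dist_quantile`; scalar for
#'   `max_lifespan`).
#' @return Probabilities or times in days.
#' @examples
#' max_lifespan(logistic_dist(20, 2)) # 20 + 2*log(99), about 29.19 d
#' @export
dist_survival <- function(dist, t) {
  stopifnot(inherits(dist, "lifespan_dist"))
  switch(dist$family,
    logistic = logistic_survival(t, dist$mu, dist$s),
    gompertz = 1 - gompertz_cdf(t, dist$alpha, dist$beta),
    mixture = {
      out <- 0
      for (i in seq_along(dist$weights)) {
        out <- out + dist$weights[i] * dist_survival(dist$components[[i]], t)
      }
      out
    })
}

#' @rdname dist_survival
#' @export
dist_cdf <- function(dist, t) 1 - dist_survival(dist, t)

#' @rdname dist_survival
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "lifespan_dist"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  switch(dist$family,
    logistic = logistic_quantile(p, dist$mu, dist$s, type = "cdf"),
    gompertz = gompertz_quantile(p, dist$alpha, dist$beta),
    mixture = vapply(p, function(pp) {
      # bracket the root of F(t) = pp over the component quantile range
      lo <- min(vapply(dist$components, dist_quantile, numeric(1), p = pp)) - 1
      hi <- max(vapply(dist$components, dist_quantile, numeric(1), p = pp)) + 1
      stats::uniroot(function(t) dist_cdf(dist, t) - pp, c(lo, hi),
                     tol = 1e-10)$root
    }, numeric(1)))
}

#' @rdname dist_survival
#' @export
max_lifespan <- function(dist, p = 0.99) {
  stopifnot(length(p) == 1L)
  dist_quantile(dist, p)
}

#' Draw simulated animal death times
#'
#' Inverse-transform sampling: uniform draws are used as quantiles of the
#' generating distribution. For mixtures the component of each animal is first
#' chosen according to the mixture weights. Uses the current R random number
#' stream.
#'
#' @param n Number of animals (positive integer).
#' @param dist Generating distribution.
#' @return Numeric vector of `n` death times in days.
#' @examples
#' set.seed(1)
#' median(sample_death_times(1e4, logistic_dist(20, 2)))
#' @export
sample_death_times <- function(n, dist) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(inherits(dist, "lifespan_dist"))
  if (dist$family == "mixture") {
    comp <- sample.int(length(dist$weights), n, replace = TRUE,
                       prob = dist$weights)
    u <- stats::runif(n)
    out <- numeric(n)
    for (i in seq_along(dist$weights)) {
      sel <- comp == i
      if (any(sel)) out[sel] <- dist_quantile(dist$components[[i]], u[sel])
    }
    out
  } else {
    dist_quantile(dist, stats::runif(n))
  }
}
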