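# Two-sample tests across designs, and Monte-Carlo power analysis.

expand_records <- function(data) {
  data <- as_interval_data(data)
  idx <- rep.int(seq_len(nrow(data)), data$weight)
  data.frame(left = data$left[idx], right = data$right[idx])
}

#' Mantel-Cox log-rank test
#'
#' Standard log-rank comparison of two groups of exact event times with
#' optional right censoring, via [survival::survdiff()]. This is the
#' appropriate test for the right-censored treatment of traditional
#' longitudinal (TLM) data; it cannot be applied to current-status RSM data.
#'
#' @param group_a,group_b [interval_data()] objects containing only exact
#'   events (`left == right`) and right-censored records, or plain numeric
#'   vectors of event times.
#' @return A list with `p_value`, `chisq` and `df`.
#' @examples
#' logrank_test(c(10, 12, 15, 20), c(14, 18, 22, 25))
#' @export
logrank_test <- function(group_a, group_b) {
  as_events <- function(g, label) {
    if (is.numeric(g)) g <- interval_data(g, g)
    g <- as_interval_data(g)
    exact <- g$left == g$right
    rc <- is.infinite(g$right)
    if (!all(exact | rc)) {
      stop("log-rank requires exact or right-censored records; ",
           "use interval_twosample_test() for interval-censored data",
           call. = FALSE)
    }
    if (!any(exact)) stop("group ", label, " has no events", call. = FALSE)
    r <- expand_records(g)
    data.frame(time = ifelse(is.finite(r$right), r$right, r$left),
               status = as.numeric(is.finite(r$right)))
  }
  a <- as_events(group_a, "a")
  b <- as_events(group_b, "b")
  dat <- rbind(a, b)
  dat$group <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = dat)
  df <- length(sd$n) - 1
  list(p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       chisq = sd$chisq, df = df)
}

# right-continuous evaluation of a pooled NPMLE step curve at arbitrary times
step_surv <- function(curve, t) {
  out <- rep(1, length(t))
  if (length(curve$time)) {
    pos <- findInterval(t, curve$time)
    out[pos > 0] <- curve$survival[pos[pos > 0]]
  }
  out[is.infinite(t) & t > 0] <- 0
  out
}

#' Permutation generalized log-rank test for interval-censored data
#'
#' Two-sample test for arbitrarily interval-censored (including
#' current-status) data. Log-rank scores are computed for every record under
#' the pooled Turnbull NPMLE: an interval `(L, R]` receives the score
#' `(S(L) log S(L) - S(R) log S(R)) / (S(L) - S(R))` with `S` the pooled
#' estimate (and `x log x := 0` at 0). The test statistic is the centred sum
#' of scores in the first group; its null distribution is obtained by
#' permuting group labels over the pooled records, and
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permuted statistics at
#' least as extreme as the observed one. Uses the current RNG stream.
#'
#' @param group_a,group_b [interval_data()] objects.
#' @param n_perm Number of label permutations.
#' @return A list with `p_value`, `statistic` (the centred score sum) and
#'   `n_perm`.
#' @export
interval_twosample_test <- function(group_a, group_b, n_perm = 999) {
  a <- expand_records(group_a)
  b <- expand_records(group_b)
  pooled <- interval_data(c(a$left, b$left), c(a$right, b$right))
  curve <- npmle_interval(pooled)
  xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))
  score1 <- function(l, r) {
    sl <- step_surv(curve, l)
    sr <- step_surv(curve, r)
    d <- sl - sr
    ifelse(d <= 1e-12, 0, (xlogx(sl) - xlogx(sr)) / d)
  }
  sc <- c(score1(a$left, a$right), score1(b$left, b$right))
  n_a <- nrow(a)
  n_tot <- length(sc)
  obs <- abs(sum(sc[seq_len(n_a)]) - n_a * mean(sc))
  perm <- vapply(seq_len(n_perm), function(i) {
    abs(sum(sc[sample.int(n_tot, n_a)]) - n_a * mean(sc))
  }, numeric(1))
  b_count <- sum(perm >= obs - 1e-12)
  list(p_value = (b_count + 1) / (n_perm + 1), statistic = obs,
       n_perm = n_perm)
}

#' Label-permutation test on fitted logistic medians
#'
#' Parametric two-sample comparison: each group is fitted by the logistic
#' interval MLE and the test statistic is the absolute difference of fitted
#' location parameters (the fitted median lifespans),
#' `|mu_a - mu_b|`. The null distribution is generated by permuting
#' animal-level labels across the pooled records — each record keeping its
#' own event interval — and refitting both groups;
#' `p = (b + 1) / (n_perm + 1)`. Permutations whose refit fails are counted
#' as exceeding the observed statistic (conservative); if more than 1% of
#' permutations fail the test aborts. Uses the current RNG stream.
#'
#' @param group_a,group_b [interval_data()] objects, each identifiable for
#'   logistic fitting.
#' @param n_perm Number of label permutations.
#' @return A list with `p_value`, `statistic` (`|mu_a - mu_b|`, days),
#'   `mu_a`, `mu_b`, `n_perm` and `n_failed`.
#' @export
permutation_test_parametric <- function(group_a, group_b, n_perm = 999) {
  a <- expand_records(group_a)
  b <- expand_records(group_b)
  recs <- rbind(a, b)
  n_a <- nrow(a)
  n_tot <- nrow(recs)
  key <- interaction(recs$left, recs$right, drop = TRUE)
  k <- as.integer(key)
  nk <- nlevels(key)
  first <- match(seq_len(nk), k)
  ul <- recs$left[first]
  ur <- recs$right[first]
  w_tot <- tabulate(k, nk)
  pooled <- interval_data(recs$left, recs$right)
  mu0 <- default_mu0(pooled)

  fit_sub <- function(w) {
    sel <- w > 0
    if (!any(is.finite(ur[sel])) || !any(ul[sel] > 0)) return(NULL)
    f <- logistic_mle_core(ul[sel], ur[sel], w[sel], mu0)
    if (f$converged) f$mu else NULL
  }
  w_a_obs <- tabulate(k[seq_len(n_a)], nk)
  mu_a <- fit_sub(w_a_obs)
  mu_b <- fit_sub(w_tot - w_a_obs)
  if (is.null(mu_a) || is.null(mu_b)) {
    stop("logistic fit failed on an observed group; groups must be ",
         "identifiable", call. = FALSE)
  }
  obs <- abs(mu_a - mu_b)
  n_failed <- 0L
  b_count <- 0L
  for (i in seq_len(n_perm)) {
    ia <- sample.int(n_tot, n_a)
    w_a <- tabulate(k[ia], nk)
    pa <- fit_sub(w_a)
    pb <- fit_sub(w_tot - w_a)
    if (is.null(pa) || is.null(pb)) {
      n_failed <- n_failed + 1L
      b_count <- b_count + 1L # conservative
    } else if (abs(pa - pb) >= obs - 1e-12) {
      b_count <- b_count + 1L
    }
  }
  if (n_failed > 0.01 * n_perm) {
    stop(sprintf("logistic fit failed on %d of %d permutations", n_failed,
                 n_perm), call. = FALSE)
  }
  list(p_value = (b_count + 1) / (n_perm + 1), statistic = obs,
       mu_a = mu_a, mu_b = mu_b, n_perm = n_perm, n_failed = n_failed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p-values,
#' preserving input order ([stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) || any(p_values < 0) ||
      any(p_values > 1)) {
    stop("`p_values` must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Power as the fraction of significant comparisons
#'
#' @param adjusted_p Vector of (FDR-adjusted) p-values.
#' @param alpha Significance level; p-values strictly below count.
#' @return Fraction of p-values below `alpha`.
#' @examples
#' power_from_pvalues(c(0.005, 0.02, 0.5, 0.005), alpha = 0.01)
#' @export
power_from_pvalues <- function(adjusted_p, alpha = 0.01) {
  if (!length(adjusted_p)) stop("empty p-value vector", call. = FALSE)
  mean(adjusted_p < alpha)
}

#' Monte-Carlo power analysis across designs and effect sizes
#'
#' For every combination of design, analysis, sample size and test-group
#' median, simulates `n_trials` independent pairs of trials — a test trial
#' with the given median and a reference trial at `ref_median` days, both
#' logistic with shape `s` — compares each pair with the analysis-appropriate
#' test, adjusts the `n_trials` p-values by Benjamini-Hochberg within the
#' cell, and reports the fraction below `alpha` together with the median
#' total number of animal observations per test trial (the effort proxy).
#' Each cell runs on its own L'Ecuyer-CMRG substream of `master_seed`.
#'
#' @param designs Character subset of `c("TLM", "RSM")`.
#' @param analyses Character subset of `c("km_right", "npmle_interval",
#'   "logistic")`; `km_right` (log-rank) applies to TLM only.
#' @param sample_sizes Animals per trial (TLM) or per observation (RSM).
#' @param effect_medians Test-group median lifespans, days.
#' @param n_trials Comparisons per cell.
#' @param master_seed Integer seed.
#' @param ref_median Reference median lifespan, days.
#' @param s Logistic shape parameter, days.
#' @param interval Scoring interval, days.
#' @param n_perm Permutations for the permutation-based tests.
#' @param alpha Significance level applied to adjusted p-values.
#' @return A data.frame with one row per cell: `design`, `analysis`,
#'   `sample_size`, `effect_median`, `n_trials`, `alpha`, `power`,
#'   `median_total_observations`.
#' @export
power_grid <- function(designs = c("TLM", "RSM"),
                       analyses = "logistic",
                       sample_sizes = c(TLM = 110, RSM = 20),
                       effect_medians = c(18, 20, 22),
                       n_trials = 100, master_seed = 1,
                       ref_median = 20, s = 2, interval = 1,
                       n_perm = 999, alpha = 0.01) {
  designs <- match.arg(designs, c("TLM", "RSM"), several.ok = TRUE)
  analyses <- match.arg(analyses, c("km_right", "npmle_interval", "logistic"),
                        several.ok = TRUE)
  if (n_trials < 10) stop("`n_trials` must be at least 10", call. = FALSE)
  if (1 / (n_perm + 1) >= alpha) {
    warning(sprintf(
      "permutation p-values cannot fall below 1/(n_perm+1) = %.4g >= alpha = %g; ",
      1 / (n_perm + 1), alpha), "increase n_perm to make rejection possible",
      call. = FALSE)
  }
  cells <- expand.grid(design = designs, analysis = analyses,
                       effect_median = effect_medians,
                       stringsAsFactors = FALSE)
  cells <- cells[!(cells$design == "RSM" & cells$analysis == "km_right"), ]
  seeds <- trial_seeds(master_seed, nrow(cells))
  old <- rng_snapshot()
  on.exit(rng_restore(old))
  rows <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    assign(".Random.seed", seeds[[j]], envir = globalenv())
    design <- cells$design[j]
    analysis <- cells$analysis[j]
    n <- if (!is.null(names(sample_sizes))) {
      unname(sample_sizes[[design]])
    } else {
      sample_sizes[1]
    }
    d_test <- logistic_dist(cells$effect_median[j], s)
    d_ref <- logistic_dist(ref_median, s)
    pvals <- numeric(n_trials)
    effort <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      if (design == "TLM") {
        tr_test <- run_tlm_trial(n, d_test, interval)
        tr_ref <- run_tlm_trial(n, d_ref, interval)
        ga <- tlm_to_intervals(tr_test,
                               if (analysis == "km_right") "right" else "interval")
        gb <- tlm_to_intervals(tr_ref,
                               if (analysis == "km_right") "right" else "interval")
      } else {
        tr_test <- run_rsm_trial(n, d_test, interval)
        tr_ref <- run_rsm_trial(n, d_ref, interval)
        ga <- rsm_to_intervals(tr_test)
        gb <- rsm_to_intervals(tr_ref)
      }
      effort[i] <- count_observations(tr_test)
      pvals[i] <- switch(analysis,
        km_right = logrank_test(ga, gb)$p_value,
        npmle_interval = interval_twosample_test(ga, gb, n_perm)$p_value,
        logistic = permutation_test_parametric(ga, gb, n_perm)$p_value)
    }
    rows[[j]] <- data.frame(
      design = design, analysis = analysis, sample_size = n,
      effect_median = cells$effect_median[j], n_trials = n_trials,
      alpha = alpha, power = power_from_pvalues(bh_adjust(pvals), alpha),
      median_total_observations = stats::median(effort))
  }
  do.call(rbind, rows)
}
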