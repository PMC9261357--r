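test_that("TLM trials convert to the documented event intervals", {
  trial <- make_tlm_trial(recorded = c(6, 6, 8))
  di <- tlm_to_intervals(trial, "interval")
  expect_equal(di$left, c(5, 7))
  expect_equal(di$right, c(6, 8))
  expect_equal(di$weight, c(2, 1))
  dr <- tlm_to_intervals(trial, "right")
  expect_equal(dr$left, dr$right)
  expect_equal(dr$right, c(6, 8))
  # first-observation death under 2-day scoring opens at 0
  t2 <- make_tlm_trial(recorded = c(2, 4), interval = 2)
  expect_equal(tlm_to_intervals(t2, "interval")$left, c(0, 2))
})

test_that("RSM trials convert to current-status intervals", {
  trial <- make_rsm_trial(times = 10, n_live = 3, n_dead = 2)
  d <- rsm_to_intervals(trial)
  expect_equal(d$left, c(0, 10))
  expect_equal(d$right, c(10, Inf))
  expect_equal(d$weight, c(2, 3))
  # hand-constructed two-observation current-status dataset
  t2 <- make_rsm_trial(times = c(5, 25), n_live = c(2, 0), n_dead = c(0, 2))
  d2 <- rsm_to_intervals(t2)
  expect_equal(nrow(d2), 2) # (0,25] x2 and (5,Inf) x2 after aggregation
  expect_equal(sum(d2$weight), 4)
})

test_that("interval_data validates and aggregates", {
  d <- interval_data(c(0, 0, 5), c(3, 3, Inf), c(1, 2, 1))
  expect_equal(nrow(d), 2)
  expect_equal(d$weight[d$right == 3], 3)
  expect_error(interval_data(5, 3), "left <= right")
  expect_error(interval_data(0, 3, weight = 0), "positive")
  expect_error(interval_data(Inf, Inf), "finite|reverse")
})

test_that("logistic MLE recovers parameters from binned draws", {
  set.seed(11)
  x <- sample_death_times(1e4, ref_dist())
  rec <- pmax(ceiling(x), 0)
  d <- interval_data(pmax(rec - 1, -Inf), rec)
  fit <- fit_logistic_mle(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_hat - 20), 0.1)
  expect_lt(abs(fit$s_hat - 2), 0.1)
  expect_equal(fit$median, fit$mu_hat)
  expect_equal(fit$mean, fit$mu_hat)
  expect_equal(fit$q95, fit$mu_hat + fit$s_hat * log(19))
})

test_that("a symmetric two-interval dataset forces mu = 20", {
  # counts symmetric about 20: the likelihood is symmetric in mu, so the
  # location estimate lands exactly at the midpoint
  d <- interval_data(c(-Inf, 18, 22), c(18, 22, Inf), c(3, 4, 3))
  fit <- fit_logistic_mle(d)
  expect_true(fit$converged)
  expect_equal(fit$mu_hat, 20, tolerance = 1e-4)
})

test_that("fits are invariant to weight scaling", {
  d1 <- interval_data(c(0, 0, 19, 23), c(19, 23, Inf, Inf), c(3, 8, 6, 2))
  d5 <- interval_data(d1$left, d1$right, d1$weight * 5)
  f1 <- fit_logistic_mle(d1)
  f5 <- fit_logistic_mle(d5)
  expect_equal(f5$mu_hat, f1$mu_hat, tolerance = 1e-5)
  expect_equal(f5$s_hat, f1$s_hat, tolerance = 1e-5)
  expect_equal(f5$loglik, 5 * f1$loglik, tolerance = 1e-6)
})

test_that("non-identifiable data is flagged instead of fitted", {
  all_live <- interval_data(c(5, 10), c(Inf, Inf), c(3, 3))
  fit <- fit_logistic_mle(all_live)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "non-identifiable")
  all_dead <- interval_data(c(0, 0), c(5, 10), c(3, 3))
  expect_false(fit_logistic_mle(all_dead)$converged)
})

test_that("parameter recovery holds across generating locations", {
  for (mu in c(16, 20, 24)) {
    trials <- run_trial_set(150, master_seed = mu, "RSM", n = 20,
                            dist = logistic_dist(mu, 2))
    mhat <- fitted_medians(trials)
    expect_lt(abs(mean(mhat) - mu), 0.1)
  }
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  curve <- km_right_censored(interval_data(1:4, 1:4))
  expect_equal(curve$time, 1:4)
  expect_equal(curve$survival, c(0.75, 0.5, 0.25, 0))
  s <- curve_summaries(curve)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2.5)
  # point mass: all summaries collapse to the common event time
  pm <- km_right_censored(interval_data(rep(5, 8), rep(5, 8)))
  sp <- curve_summaries(pm)
  expect_equal(sp$median, 5)
  expect_equal(sp$mean, 5)
  expect_equal(sp$q95, 5)
  # censoring is honoured: censored-after-last-event leaves the tail up
  cen <- km_right_censored(interval_data(c(1, 2, 3), c(1, 2, Inf)))
  expect_equal(suppressWarnings(curve_summaries(cen))$median, 2)
})

test_that("Kaplan-Meier refuses genuinely interval-censored data", {
  d <- interval_data(c(0, 5), c(5, Inf), c(2, 2))
  expect_error(km_right_censored(d), "current-status|interval")
  expect_error(km_right_censored(interval_data(c(5, 10), c(Inf, Inf))),
               "no events")
})

test_that("NPMLE reduces to Kaplan-Meier on exact event times", {
  set.seed(21)
  x <- ceiling(sample_death_times(200, ref_dist()))
  km <- km_right_censored(interval_data(x, x))
  np <- npmle_interval(interval_data(x, x))
  expect_equal(np$time, km$time)
  expect_equal(np$survival, km$survival, tolerance = 1e-6)
})

test_that("two-class current-status NPMLE has the closed-form masses", {
  d <- interval_data(c(0, 10), c(10, Inf), c(5, 5))
  curve <- npmle_interval(d)
  s <- suppressWarnings(curve_summaries(curve)) # q95 is undefined here
  # half the mass inside (0, 10] (midpoint 5), half beyond 10
  expect_equal(curve$survival[1], 0.5)
  expect_equal(s$median, 5)
})

test_that("interval-censored NPMLE places mass at interval midpoints", {
  trial <- make_tlm_trial(recorded = c(18, 19, 19, 20, 21, 21, 22, 23))
  curve <- npmle_interval(tlm_to_intervals(trial, "interval"))
  expect_true(all(curve$time %in% (c(18, 19, 20, 21, 22, 23) - 0.5)))
  # empirical masses: each death interval carries its share of the n animals
  expect_equal(min(curve$survival), 0, tolerance = 1e-8)
})

test_that("the NPMLE log-likelihood dominates any logistic fit", {
  set.seed(31)
  trial <- run_rsm_trial(20, ref_dist())
  d <- rsm_to_intervals(trial)
  fit <- fit_logistic_mle(d)
  curve <- npmle_interval(d)
  s_np <- function(t) wormspan:::step_surv(curve, t)
  ll_np <- sum(d$weight * log(pmax(s_np(d$left) - s_np(d$right), 1e-12)))
  expect_gte(ll_np, fit$loglik - 1e-6)
})

test_that("curve summaries of the analytic reference curve match closed forms", {
  tt <- seq(0.05, 45, by = 0.05)
  curve <- wormspan:::new_survival_curve(tt, logistic_survival(tt, 20, 2),
                                         "km_right", Inf)
  s <- curve_summaries(curve)
  expect_equal(s$median, 20, tolerance = 0.051)
  expect_equal(s$q95, 20 + 2 * log(19), tolerance = 0.051)
  expect_equal(s$mean, 20, tolerance = 0.06)
})

test_that("with zero censoring the KM median and mean equal the sample ones", {
  set.seed(41)
  x <- ceiling(sample_death_times(150, ref_dist()))
  curve <- km_right_censored(interval_data(x, x))
  s <- curve_summaries(curve)
  expect_equal(s$mean, mean(x), tolerance = 1e-8)
  # sample median under the 'smallest time with S <= 0.5' convention
  expect_equal(s$median, quantile(x, 0.5, type = 1)[[1]])
})
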