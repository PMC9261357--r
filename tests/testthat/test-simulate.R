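test_that("a single-animal TLM trial is bookkept observation by observation", {
  # force the death time near 5.5 with a near-degenerate distribution
  set.seed(1)
  trial <- run_tlm_trial(1, logistic_dist(5.5, 1e-9), interval = 1)
  obs <- trial$observations
  expect_equal(obs$time, 0:6)
  expect_equal(obs$n_live, c(rep(1L, 6), 0L))
  expect_equal(obs$n_dead, c(rep(0L, 6), 1L))
  expect_equal(trial$recorded_death_times, 6)
})

test_that("without error, recorded deaths land on the next scheduled observation", {
  for (interval in c(1, 2, 3)) {
    set.seed(interval)
    trial <- run_tlm_trial(50, ref_dist(), interval = interval)
    expected <- interval * ceiling(trial$true_death_times / interval)
    expected[expected < 0] <- 0
    expect_equal(trial$recorded_death_times, expected)
    expect_true(all(diff(trial$observations$time) == interval))
  }
})

test_that("TLM conserves animals under every error model", {
  models <- list(
    error_model("none"),
    error_model("constant", max_p = 0.1),
    error_model("late_onset", max_p = 0.1),
    error_model("mid_onset", max_p = 0.1),
    error_model("constant", effect = "hazard", max_p = 0.1),
    error_model("late_onset", effect = "hazard", max_p = 0.1))
  for (i in seq_along(models)) {
    set.seed(100 + i)
    trial <- run_tlm_trial(40, ref_dist(), 1, models[[i]])
    expect_false(trial$truncated)
    expect_equal(sum(trial$observations$n_dead), 40L)
    expect_equal(sum(!is.na(trial$recorded_death_times)), 40L)
    expect_true(all(diff(trial$observations$time) > 0))
  }
})

test_that("zero-probability mis-scoring is bit-identical to no error", {
  set.seed(5)
  a <- run_tlm_trial(30, ref_dist(), 1, error_model("none"))
  set.seed(5)
  b <- run_tlm_trial(30, ref_dist(), 1, error_model("constant", max_p = 0))
  expect_identical(a$recorded_death_times, b$recorded_death_times)
  expect_identical(a$observations, b$observations)
  set.seed(5)
  c1 <- run_rsm_trial(20, ref_dist(), 1, error_model("none"))
  set.seed(5)
  c2 <- run_rsm_trial(20, ref_dist(), 1, error_model("constant", max_p = 0))
  expect_identical(c1$observations, c2$observations)
})

test_that("error draws never perturb the death times (paired-seed discipline)", {
  set.seed(6)
  none <- run_tlm_trial(30, ref_dist(), 1, error_model("none"))
  set.seed(6)
  err <- run_tlm_trial(30, ref_dist(), 1, error_model("constant", max_p = 0.02))
  expect_identical(none$true_death_times, err$true_death_times)
  set.seed(6)
  r_none <- run_rsm_trial(15, ref_dist(), 1, error_model("none"))
  set.seed(6)
  r_err <- run_rsm_trial(15, ref_dist(), 1,
                         error_model("constant", max_p = 0.05))
  expect_identical(r_none$true_death_times, r_err$true_death_times)
})

test_that("handling hazard only shortens recorded lifespans, never extends", {
  set.seed(9)
  none <- run_tlm_trial(60, ref_dist(), 1, error_model("none"))
  set.seed(9)
  haz <- run_tlm_trial(60, ref_dist(), 1,
                       error_model("constant", effect = "hazard", max_p = 0.2))
  # same seed implies same death times; hazard can only move deaths earlier
  expect_identical(none$true_death_times, haz$true_death_times)
  expect_true(all(haz$recorded_death_times <= none$recorded_death_times))
  # a dead animal is recorded at the first observation that sees it dead
  expect_true(all(haz$recorded_death_times >= 0))
})

test_that("RSM counts are complete and plates prepared as scheduled", {
  set.seed(2)
  trial <- run_rsm_trial(20, ref_dist(), 1)
  expect_equal(trial$n_plates_prepared, ceiling(20 + 2 * log(99)) + 2) # 32
  obs <- trial$observations
  expect_true(all(obs$n_live + obs$n_dead + obs$n_censored == 20))
  expect_lte(nrow(obs), trial$n_plates_prepared)
  expect_equal(obs$time, seq_len(nrow(obs)))
})

test_that("a deterministic RSM cohort stops two observations after extinction", {
  set.seed(3)
  trial <- run_rsm_trial(5, logistic_dist(10.5, 1e-9), interval = 1)
  obs <- trial$observations
  expect_equal(obs$n_live[obs$time <= 10], rep(5L, 10))
  expect_equal(obs$n_dead[obs$time >= 11], rep(5L, 2))
  expect_equal(max(obs$time), 12)
  expect_true(trial$terminated_early)
})

test_that("trial sets are reproducible and order-independent", {
  a <- run_trial_set(4, 99, "TLM", n = 15)
  b <- run_trial_set(4, 99, "TLM", n = 15)
  expect_identical(lapply(a, `[[`, "recorded_death_times"),
                   lapply(b, `[[`, "recorded_death_times"))
  # per-trial substreams: a shorter set shares its leading trials
  c3 <- run_trial_set(2, 99, "TLM", n = 15)
  expect_identical(a[[1]]$recorded_death_times, c3[[1]]$recorded_death_times)
  expect_identical(a[[2]]$recorded_death_times, c3[[2]]$recorded_death_times)
  # RSM likewise
  r1 <- run_trial_set(3, 7, "RSM", n = 10)
  r2 <- run_trial_set(3, 7, "RSM", n = 10)
  expect_identical(lapply(r1, `[[`, "observations"),
                   lapply(r2, `[[`, "observations"))
})

test_that("run_trial_set leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(run_trial_set(2, 1, "RSM", n = 5))
  expect_identical(.Random.seed, before)
  x1 <- runif(1)
  set.seed(123)
  invisible(.Random.seed)
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("pathological mis-scoring is cut off by the safety cap", {
  # p = 0.95: dead animals are almost always re-scored as alive, so the
  # plate would take far beyond the distribution span to clear
  set.seed(4)
  trial <- run_tlm_trial(5, logistic_dist(5, 0.5),
                         error = error_model("constant", max_p = 0.95))
  expect_true(trial$truncated ||
                max(trial$observations$time) <= 10 * max_lifespan(logistic_dist(5, 0.5)) + 1)
  if (trial$truncated) {
    expect_gt(sum(trial$observations$n_censored), 0)
  }
})
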