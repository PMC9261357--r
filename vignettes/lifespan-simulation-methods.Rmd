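---
title: "Models and methods behind wormspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(wormspan)
```

wormspan simulates *C. elegans* lifespan experiments under two designs and
analyzes them with censoring handled correctly. This vignette explains the
generating models, the simulated scoring protocols, the estimators, the
testing machinery, and the numerical and design choices, so that a reader
can judge what the package's simulations do — and do not — say about real
experiments.

## Generating models

Simulated animals receive a death time by inverse-transform sampling from a
parametric model:

* **Logistic**, survival $S(t) = 1/(1 + e^{(t-\mu)/s})$, quantile
  $T(p) = s\ln(1/p - 1) + \mu$ in terms of survival probability $p$. The
  location $\mu$ is both mean and median, and $s$ controls the slope of the
  decline. Wild-type lifespan data fit this family well, and the reference
  condition throughout is $\mu = 20$ d, $s = 2$ d — a population whose
  median lifespan is 20 days and whose 99% mortality time ("expected
  maximum lifespan") is $\mu + s\ln 99 \approx 29.19$ d. The literature
  occasionally rounds this to 30 d; the package always uses the closed
  form, which is what `max_lifespan()` returns.
* **Gompertz**, $F(t) = 1 - \exp\{(\alpha/\beta)(1 - e^{\beta t})\}$ with
  baseline rate $\alpha$ and rate of aging $\beta$, quantile
  $T(p) = \ln(1 - (\beta/\alpha)\ln(1-p))/\beta$ on the death fraction $p$.
  The reference mismatch scenario uses $\alpha = 0.0003271342$,
  $\beta = 0.3271342007$, chosen so the median is exactly 20 d with a slope
  comparable to the reference logistic. Gompertz is generate-only: the
  parametric fitter is deliberately logistic, to study what happens when
  the fitted family is wrong.
* **Mixtures** of the above model systemic errors such as strain
  contamination, e.g. `make_mixture(0.67, logistic_dist(20, 2),
  logistic_dist(16, 1.6))`. The mixture median solves
  $\sum_k w_k S_k(t) = 1/2$; for that contamination scenario it is 18.62 d
  (`dist_quantile(mix, 0.5)`).

## The two designs, as simulated

**TLM** (traditional longitudinal method): one plate of $N$ animals scored
at $t = 0, \Delta, 2\Delta, \dots$; animals scored dead are removed; the
trial ends when the plate is empty. The schedule includes a day-0 baseline
observation — the count of the freshly plated population — which matters
for effort accounting and gives time-constant error models their first
opportunity to strike. Without scoring error, an animal dying at true time
$x$ is recorded at the first scheduled observation $\ge x$.

**RSM** (replica set method): $T$ plates of $N$ animals are prepared at
setup, with $T = \lceil T_{99}/\Delta\rceil + 2$ reaching two observations
past the 99% mortality time of the generating model (32 plates for the
reference condition at daily scoring). Plate $k$ is scored once at
$t = k\Delta$, then discarded, so the data are *current-status*: each
animal is inspected exactly once and contributes only alive/dead at its
inspection time. The recorded experiment ends two observations after the
last observation showing any live animal (the "two consecutive empty
observations" rule, applied to the prepared schedule), or when plates run
out. Under mis-scoring, a dead animal called alive near the end extends
the record — the "reset the clock" behaviour this termination rule is
known for.

Simulations generate no censored animals (`n_censored` exists for real
data I/O); crawl-off, food depletion, progeny and temperature effects are
out of scope.

### Scoring-error models

`error_model()` describes two distinct effects, never combined in one
trial. *Mis-scoring* flips the recorded status with probability $P(t)$: in
TLM a live animal called dead is removed (the error propagates — its
lifespan is permanently shortened), while a dead animal called alive stays
and is re-assessed with a fresh draw at the next observation (the error
usually heals). *Hazard* kills a truly live animal with probability $P(t)$
at the moment of scoring, modelling damage from prodding fragile animals.

$P(t)$ is constant, or rises from zero to `max_p` along the logistic CDF
$F$ of the reference distribution: `late_onset` uses $P(t) = p_{max}F(t)$
(the error rate mirrors the decline in survival), and `mid_onset` uses
$P(t) = p_{max}F(1.5t)$, shifting the rise earlier to track the loss of
mobility that precedes the bulk of mortality. This reconstruction — CDF
shape, $1.5t$ time-scaling for the mid-life curve — is the reading under
which simulated TLM/RSM estimates reproduce the reported benchmark values
(e.g. 16.8 d for TLM at a constant 2% rate; 20.07 d for RSM at a 2%
mid-life-onset rate); the tests treat a systematic miss on those values as
evidence against the curve reading rather than the simulator.

### Randomness

Death times are drawn first; then every animal-observation consumes exactly
one uniform draw for the error decision *regardless of the error
probability*, so that runs with and without error under one seed share
death times (this enables paired comparisons). Trial sets draw per-trial
substreams from a master seed with the L'Ecuyer-CMRG generator
(`parallel::nextRNGStream()`), making results independent of execution
order; `run_trial_set()` restores the caller's RNG state afterwards.

## Estimation

`tlm_to_intervals()` and `rsm_to_intervals()` convert trials to weighted
event intervals $(l, r]$ — half-open by convention, so a death recorded at
an observation belongs to the interval ending there. TLM deaths become
$(t-\Delta, t]$ (interval mode) or exact times $t$ (right mode, the
assumption right-censored software makes); RSM animals become $(0, t]$ if
dead and $(t, \infty)$ if alive. Day-0 TLM deaths, which only mis-scoring
can produce, get $(-\infty, 0]$.

Three analysis treatments:

* **Kaplan-Meier** (`km_right_censored()`, via `survival::survfit`) for
  exact/right-censored data. It refuses true interval data, including
  current-status data, which the product-limit estimator cannot represent.
* **Turnbull NPMLE** (`npmle_interval()`, via `survival::survfit` on an
  `interval2` response) for general interval censoring. Mass inside a
  Turnbull interval is summarized at its midpoint — a convention, stated
  as such, since the NPMLE only determines the mass per equivalence class.
* **Parametric logistic MLE** (`fit_logistic_mle()`), maximizing
  $\sum_i w_i \ln\{S(l_i) - S(r_i)\}$ over $(\mu, \log s)$ with
  `stats::nlm` and an analytic gradient. $S(0)$ is evaluated, not forced
  to 1 (immaterial at the reference parameters, where $S(0) > 0.9999$).
  Initialization uses the weighted median of finite right edges for $\mu$
  and $s_0 = 2$, with retries from perturbed starts; data with no observed
  death or no animal seen alive are flagged non-identifiable instead of
  fitted. The fit reports median = mean = $\hat\mu$ and
  $q_{95} = \hat\mu + \hat s\ln 19$.

`curve_summaries()` takes median and $q_{95}$ as the earliest time the
curve falls to 0.5/0.05 (ties toward the earlier time) and the mean as the
restricted mean survival time up to the last mass point — inactive
restriction for simulated trials, which end in full mortality.

Two discretization facts are worth knowing when interpreting summaries.
With daily scoring, per-trial KM medians live on the integer grid (the
right-censoring bias of ~half the scoring interval therefore shows up in
the *mean* of per-trial medians, or in the per-trial mean estimates, not
in a median of integer medians). Similarly the NPMLE median at a 3-day
interval can only land on midpoints of 3-day classes.

## Two-sample testing and power

* `logrank_test()`: Mantel-Cox via `survival::survdiff`, for
  right-censored treatments.
* `interval_twosample_test()`: generalized log-rank for interval-censored
  data. Scores are computed under the pooled NPMLE
  ($\{S(l)\ln S(l) - S(r)\ln S(r)\}/\{S(l) - S(r)\}$ per record) and the
  null distribution is generated by label permutation. The variant is a
  design choice (score type and permutation reference distribution differ
  across implementations in the literature); the permutation form was
  chosen because it is exact under exchangeability and needs no asymptotic
  variance.
* `permutation_test_parametric()`: the RSM-style test. The statistic is
  $|\hat\mu_a - \hat\mu_b|$ from separate logistic fits — the quantity the
  analysis reports — and labels are permuted at the level of individual
  animal records, preserving each design's observation structure. All
  permutation p-values use $(b+1)/(n_{perm}+1)$, so $p \ge 1/(n_{perm}+1)$
  by construction.

`power_grid()` compares test-group trials against fresh reference trials
(median 20 d) at matched design and sample size, adjusts p-values by
Benjamini-Hochberg *within* each cell of trials (the FDR family is the
set of like-for-like comparisons, not the whole grid), and reports the
fraction below $\alpha = 0.01$ plus the median total animal observations —
the effort proxy, which counts every assessment of every animal including
TLM re-assessments and the day-0 baseline.

## Problem sizes and what the tests show

The package's own acceptance checks run 1,000 trials per condition — a
size at which every tolerance used (0.15–0.5 d on medians, 5% on
observation counts) comfortably exceeds the Monte-Carlo noise — and
100–150 trial pairs per power cell with up to a thousand permutations.
At the matched sizes the per-comparison dispersion of fitted medians
(about 0.3 d for both designs) caps the per-trial rejection rate at
roughly 0.95–0.98 for a 2-day effect at $\alpha = 0.01$; "full" power —
every adjusted p-value significant — is reached by the RSM once the
per-observation sample grows modestly, still at well under half the
TLM's observation effort, and the power checks assert exactly that. Null
calibration of the permutation tests is checked against a $1.5\alpha$
ceiling with a two-standard-error Monte-Carlo allowance for the finite
number of null trials (1,000 pairs for the cheap tests, 320 where each
trial performs hundreds of refits).

Passing these checks shows that the *simulated* designs reproduce the
documented biases, error responses and power at desk scale. It does not
validate the biology of the error curves (their shape is a modelling
choice), nor cover censoring, environmental fluctuation, or plate-level
effects absent from the generator; conclusions about real assays inherit
the generating assumptions (i.i.d. animals, logistic or Gompertz
mortality, error independent across animals and observations).

## Known limitations

* The logistic fitter is the only parametric family, by design; it is the
  analysis whose robustness is under study.
* The NPMLE mean/median depend on the midpoint convention within Turnbull
  classes; other conventions shift summaries by up to half a class width.
* `power_grid()` holds the reference median at 20 d; comparing two
  non-reference conditions requires calling the tests directly.
* Permutation tests with small `n_perm` cannot reject below
  $1/(n_{perm}+1)$; choose `n_perm` with the target $\alpha$ in mind.

## A worked example

```{r example}
trials <- run_trial_set(50, master_seed = 7, design = "RSM", n = 20)
est <- fit_trials(trials, "logistic")
summarize_trial_set(est, true_median = 20)
```
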