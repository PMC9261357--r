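Package: wormspan
Title: Simulation and Censoring-Aware Analysis of C. elegans Lifespan Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation and statistical analysis of C. elegans
    lifespan experiments under two designs: the traditional longitudinal
    method (TLM), in which one cohort is repeatedly scored and dead animals
    removed, and the replica set method (RSM), in which independent replicate
    plates are each scored once, yielding current-status data. Provides
    logistic, Gompertz and mixture generating distributions; models of
    experimenter mis-scoring and handling hazard; censoring-aware estimation
    of median, mean and 95% quantile lifespan by Kaplan-Meier, Turnbull NPMLE
    and parametric logistic maximum likelihood on interval data; two-sample
    tests (log-rank, generalized log-rank for interval censoring, and label
    permutation on fitted medians) with Benjamini-Hochberg correction; and
    Monte-Carlo power analysis across designs, sample sizes and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    withr,
    optparse
Config/testthat/edition: 3
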