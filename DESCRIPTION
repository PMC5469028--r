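Package: discountr
Title: Hierarchical Bayesian Modelling of Temporal Discounting Choice Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intertemporal-choice experiments in which participants
    choose between a fixed smaller-sooner amount and delayed larger-later
    rewards, optionally cued with personal future-event tags. Provides the
    four standard valuation models (hyperbolic, exponential discounted
    utility, constant sensitivity, and the intertemporal choice heuristic)
    with a softmax choice rule; hierarchical Bayesian estimation of
    per-participant, per-condition discount rates and decision noise via
    MCMC; WAIC model comparison from the trials-by-samples pointwise
    log-likelihood matrix; indifference-point-based trial design for
    two-condition (episodic vs. control) sessions; synthetic two-group
    cohort simulation with retained ground truth for recovery studies; and
    the group-level behavioural statistics pipeline (tag-effect,
    mixed-design ANOVA, severity correlation, tag-effect regression,
    proportion comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
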