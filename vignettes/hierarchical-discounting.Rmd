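---
title: "Hierarchical Bayesian modelling of episodic-tag temporal discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian modelling of episodic-tag temporal discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, priors, design constants and
validation strategy behind `discountr`, and the reasoning behind the
choices that were genuinely open.

## The probability model

A trial offers a fixed immediate 20 euros against a larger-later (LL)
reward of `A` euros in `D` days (delays are in days everywhere; configs
accept no other unit). Four candidate models of the choice are
implemented:

* **Hyperbolic**: `SV = A / (1 + kD)`. One discount rate `k` per day;
  larger `k` = steeper discounting = more impulsive.
* **Exponential (discounted utility)**: `SV = A exp(-kD)`.
* **Constant sensitivity**: `SV = A exp(-(kD)^s)`, a two-parameter
  family whose time-sensitivity exponent `s` bends the delay axis; it
  reduces exactly to the exponential model at `s = 1`.
* **Intertemporal choice heuristic (ITCH)**: a logistic choice rule on
  the absolute and relative amount and delay differences between the two
  options, with an intercept and four slope weights.

The exponential, constant-sensitivity and ITCH parameterisations follow
the forms standard in the discounting literature; they are fixed
documented constants of this package. One consequence of the present
design is worth noting: because the immediate option has zero delay, the
ITCH relative-delay regressor `(D2 - D1)/mean(D1, D2)` equals 2 on every
trial with a delayed option, so its weight is only identified jointly
with the intercept. The package keeps the regressor for fidelity to the
general rule and defines it as 0 when the two delays are equal.

Value-based models are mapped to choice probabilities by the softmax
rule with temperature `β` (euros),
`p(LL) = exp(SV_LL/β) / (exp(SV_SS/β) + exp(SV_LL/β))`. The
implementation evaluates the algebraically identical logistic of
`(SV_LL - SV_SS)/β`, which cannot overflow when `β` is small. Choice
probabilities are clamped to `[1e-12, 1 - 1e-12]` before logs (and to
`[1e-9, 1 - 1e-9]` inside the sampler, where a probability rounded to
exactly 1.0 against an observed 0 would otherwise be an inconsistent
Bernoulli node), keeping every pointwise log-likelihood finite under
extreme parameter draws.

## Hierarchical estimation

`fit_hierarchical()` estimates one parameter set per participant per
condition. Individual parameters live on the log scale (`log k`,
`log β`, `log s`), matching the strong right skew of discount rates, and
are drawn from normal distributions specific to each group-by-condition
cell, so pathological gamblers and controls (and the episodic and
control conditions) have separate means and spreads but shrink their own
members. Both groups are fitted in one joint model; nothing is shared
across cells except the hyperprior constants, so this is equivalent to
separate per-group hierarchies while keeping a single log-likelihood
matrix for model comparison.

Hyperpriors (package choices — weakly informative on purpose):

| parameter | prior | rationale |
|---|---|---|
| cell mean of `log k` | Normal(−4.5, 2) | ±2 SD spans k from ~2e-4 to ~0.6 per day, covering shallow to very steep discounting |
| cell SD of `log k` | half-Normal(2) | allows order-of-magnitude individual spread without forcing it |
| cell mean of `log β` | Normal(1, 2) | β around e ≈ 2.7 euros; ±2 SD spans near-deterministic to near-random choice |
| cell SD of `log β` | half-Normal(2) | as above |
| cell mean of `log s` | Normal(0, 1) | centred on the exponential special case s = 1 |
| cell SD of `log s` | half-Normal(1) | |
| ITCH weight means | Normal(0, 5) | regressors are in euros/days; weights beyond ±10 saturate every choice |
| ITCH weight SDs | half-Normal(2) | |

These scales are broad relative to the likelihood of a 100+ trial
session, so they regularise without dominating; with information-free
(coin-flip) choices the posterior for an individual `log k` reproduces
its marginal prior, which the test suite checks by Monte Carlo.

Sampling runs in JAGS (the de-facto standard Gibbs sampler for this
model family) with defaults of 4 chains × 1000 kept draws after 1000
warmup iterations, a fixed seed recorded in the fit metadata, and
initial values at the hyperprior means. Convergence gates default to
split-R-hat ≤ 1.01 and effective sample size ≥ 400 for every sampled
parameter; a fit outside the gates is returned flagged
(`converged = FALSE`) with a warning, never silently. The pointwise
log-likelihood matrix (trials × kept samples) is recomputed in R from
the stored draws through the same likelihood code used everywhere else,
so `loglik_matrix(fit)` always reproduces `fit$loglik` exactly.

Rows with missing values in required columns are dropped with a warning
and never imputed; a participant with no trials in a condition present
in the data is a validation error.

## WAIC

`compute_waic()` implements the standard estimator on the deviance
scale: `lppd = Σ_i log mean_s exp(ℓ_is)` (evaluated via log-sum-exp),
`p_waic = Σ_i var_s(ℓ_is)` with the `n − 1` sample variance (the
variance form, which is the recommended one in the WAIC literature; the
mean-difference form is not offered), and `waic = −2(lppd − p_waic)`.
A single-sample matrix therefore has `p_waic = 0` by construction.
Duplicating a sample column changes the result only through the `n − 1`
denominator, which the tests pin down against a brute-force double-loop
implementation.

## Trial design

`build_trials()` reproduces the two-condition session structure from a
pretest discount rate and a participant's list of five to seven future
events (delays from a few days to about 200):

* Half of each condition's LL amounts form an exact evenly spaced grid
  over 20.5–99.5 euros.
* The other half are drawn Normal(indifference amount, 4 euros), where
  the indifference amount `20(1 + kD)` is the LL amount a hyperbolic
  discounter with the pretest `k` values exactly at 20 euros. Draws
  below the 20.5-euro range minimum are resampled (the source design is
  silent here; resampling keeps every offer a genuine larger-later
  reward), and the realised truncation rate is recorded in the trial
  set's provenance attribute.
* Episodic delays cycle through the event list and carry the event's
  tag; control trials are untagged.
* Control delays are whole days between one day and the maximum
  episodic delay. The statement that the two conditions "alternate in
  their time distance" is ambiguous; the default interpretation draws
  one control delay uniformly inside each gap between consecutive
  sorted episodic delays and the remainder uniformly over the full
  range, so control delays interleave the episodic ones. A pure-uniform
  fallback (`control_delay_mode = "uniform"`) is provided.
* Trial order is shuffled; a seeded build is bit-reproducible.

The adaptive pretest is not specified in detail by the study designs
this package targets, so `simulate_pretest()` implements a per-delay
bisection staircase on the LL amount (midpoint offer, bracket halves
toward the indifference point after each response) and
`pretest_estimate()` reduces any single-participant choice set to one
hyperbolic `k` by maximum likelihood with box constraints
(`k ∈ [1e-5, 2]` per day by default). An all-immediate or all-delayed
response pattern carries only one-sided information, so the estimate is
clamped to the corresponding bound with a warning rather than chasing an
unbounded optimum.

## Synthetic cohorts

`simulate_cohort()` forward-simulates the whole design: individual
`log k` and `log β` per condition from group-by-condition normals,
events and trial sets from the designer (using the participant's true
control-condition `k` as the pretest rate), choices from the generating
model's probabilities. Ground truth is always returned; a simulation
without its truth cannot serve as a recovery experiment, so none is
offered.

Default magnitudes are package choices pitched at empirically plausible
day-scale discounting, *not* estimates from any data set: control-group
mean `log k` −4.5 (median delay-halving around 90 days), a +0.7 gambler
offset, a −0.2 episodic condition shift (so the expected tag-effect is
+0.2), SD 1 across participants, `log β` mean 0.7 and SD 0.5, and a 0.7
correlation between a participant's two condition-specific parameters
(the same person under two framings is similar but not identical). The
cohort size defaults (24 per group, 120 trials) mirror the two-group
fMRI design this pipeline targets. A placeholder severity covariate
(higher in gamblers) stands in for clinical instrument scores;
`severity_score()` builds the z-average composite when raw instrument
scores exist.

What the generator deliberately does **not** emulate: reaction times,
session/fatigue effects, within-session parameter drift, non-softmax
lapses, or any neural signal. Passing recovery tests therefore shows
the estimator and comparison machinery are correct and well calibrated
under the assumed generative model — it does not certify them against
model misspecification in real data.

## Group-level statistics

The analysis pipeline consumes the per-participant, per-condition
estimate table:

* `tag_effect()` = `log(k)` control − `log(k)` episodic (positive =
  tags reduce impulsivity).
* `group_condition_anova()` is the standard mixed design (group
  between, condition within, participant as the blocking unit), run
  through `stats::aov()` with an `Error(participant)` stratum and
  checked in the tests against a hand-computed sums-of-squares
  partition. An effect with an exactly zero sum of squares reports
  F = 0, p = 1 instead of propagating a 0/0.
* `severity_correlation()` is the one-sided Pearson test for a positive
  severity–baseline-discounting association within gamblers.
* `tag_effect_regression()` fits the full predictor set (group, age,
  education, income, FTND, AUDIT, BDI, imagery, baseline `log k`) plus
  the severity-by-BDI interaction by OLS; predictors are used on their
  raw scale (no standardisation), constant columns are dropped with a
  warning, and a rank-deficient design is an error naming the collinear
  columns.
* `proportion_comparison()` is the 2×2 chi-square test of equal
  improvement proportions, with Yates' continuity correction on by
  default and configurable.
* `compare_demographics()` reports Welch (unequal-variance, fractional
  df) t-tests for group matching tables.
* No multiple-testing correction is applied across these behavioural
  tests, matching standard practice for this design's small test family.

Calibration: under null simulations the ANOVA effects and the one-sided
correlation hold their nominal 5% level within [0.04, 0.06] over 10,000
replicates (checked in the test suite). The 2×2 proportion test is
excluded from that band on purpose: a discrete test at n ≈ 30 per group
cannot attain the nominal level exactly, and the continuity-corrected
statistic is conservative by design; the right property for it — type-I
error at or below the nominal level — is what its tests assert.

## Problem sizes used in the validation suite

All heavy checks run at sizes chosen to make the full suite complete in
minutes on a single core while leaving the conclusions clearly resolved;
each is a package choice stated here once:

* Parameter recovery: one cohort of 2 groups × 12 participants × 120
  trials, hyperbolic truth, 2 chains × 400 kept draws. Pass marks: rank
  correlation of individual `log k` ≥ 0.9, absolute group-mean bias
  ≤ 0.2.
* Model recovery: 20 cohorts each from hyperbolic and exponential truth
  (4 per group × 60 trials), both models fitted at 2 × 300 draws, WAIC
  ranking correct in ≥ 80% of cohorts.
* Group-direction recovery: 20 cohorts with a +1.0 gambler offset
  (12 per group × 60 trials), fitted group means ordered correctly in
  ≥ 95%.
* Null calibration: 10,000 replicates per test at 24 participants per
  group (31 for the correlation, matching the pooled-sample sizes such
  studies report).
* Tailored-amount spread: 10,000 seeded draws at `k = 0.01`, delay 45,
  truncation disabled; empirical SD within [3.8, 4.2] euros.

## Known limitations

* MCMC only; no variational approximation path is offered.
* WAIC is the only comparison criterion (no PSIS-LOO, DIC or BIC).
* The four-model set is fixed; magnitude-dependent and quasi-hyperbolic
  (β–δ) variants are out of scope.
* The ITCH relative-delay weight is unidentified under a zero-delay
  immediate option (see above).
* Convergence gates are necessary, not sufficient; short exploratory
  runs (as in the examples) relax them explicitly and should not be
  used for inference.
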