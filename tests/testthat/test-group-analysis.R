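# estimates table builder: one row per participant x condition
est_table <- function(logk_c, logk_e, group = NULL) {
  n <- length(logk_c)
  if (is.null(group)) group <- rep(c("control", "gambler"), length.out = n)
  tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:n), 2),
    group = rep(group, 2),
    condition = rep(c("control", "episodic"), each = n),
    log_k = c(logk_c, logk_e))
}

test_that("tag-effect is control minus episodic log(k), antisymmetric in the conditions", {
  e <- est_table(c(-4, -3.5), c(-4, -4))
  te <- tag_effect(e)
  expect_equal(te$tag_effect, c(0, 0.5))
  swapped <- dplyr::mutate(e, condition =
    ifelse(condition == "control", "episodic", "control"))
  expect_equal(tag_effect(swapped)$tag_effect, -te$tag_effect)
  expect_error(tag_effect(e[-1, ]), class = "discountr_validation_error")
})

test_that("a simulated condition effect shows up in the mean tag-effect", {
  spec <- cohort_spec(n_per_group = 24, trials_per_participant = 8,
                      condition_effect = -0.2, seed = 44)
  co <- simulate_cohort(spec)
  te <- tag_effect(co$truth$params)
  se <- sd(te$tag_effect) / sqrt(nrow(te))
  expect_lt(abs(mean(te$tag_effect) - 0.2), 3 * se)
})

test_that("severity score averages within-cohort z-scores and ignores affine scale", {
  kfg <- c(10, 20, 30, 40)
  sogs <- c(1, 3, 5, 7)
  s <- severity_score(kfg, sogs)
  expect_equal(s[2] + s[3], 0) # symmetric around the cohort mean
  expect_equal(severity_score(mean(kfg), mean(sogs), kfg, sogs), 0)
  one_up <- severity_score(mean(kfg) + sd(kfg), mean(sogs) + sd(sogs),
                           kfg, sogs)
  expect_equal(one_up, 1)
  # hand-computed z-average
  expect_equal(s, ((kfg - mean(kfg)) / sd(kfg) +
                     (sogs - mean(sogs)) / sd(sogs)) / 2)
  # affine rescaling of either instrument changes nothing
  expect_equal(severity_score(3 * kfg + 7, sogs / 2 - 1), s)
  expect_error(severity_score(c(1, 1), c(1, 2)),
               class = "discountr_validation_error")
})

test_that("degenerate designs give zero F for the degenerate effect", {
  set.seed(2)
  v <- rnorm(12, -4)
  # episodic identical to control: no condition or interaction variance
  same_cond <- est_table(v, v)
  a <- group_condition_anova(same_cond)
  expect_equal(a$statistic[a$effect == "condition"], 0)
  expect_equal(a$statistic[a$effect == "group:condition"], 0)
  expect_equal(a$p.value[a$effect == "condition"], 1)
  # two groups with identical data: no group variance
  vv <- rnorm(6); ww <- rnorm(6)
  mirrored <- est_table(c(vv, vv), c(ww, ww),
                        group = rep(c("control", "gambler"), each = 6))
  a2 <- group_condition_anova(mirrored)
  expect_equal(a2$statistic[a2$effect == "group"], 0)
})

test_that("the mixed ANOVA matches a hand-computed partitioning on balanced data", {
  set.seed(5)
  for (rep in 1:4) {
    n <- 8 # per group
    e <- est_table(rnorm(2 * n, -4), rnorm(2 * n, -4.3),
                   group = rep(c("control", "gambler"), each = n))
    got <- group_condition_anova(e)
    # independent route: textbook sums-of-squares partition
    y <- e$log_k
    grand <- mean(y)
    subj <- tapply(y, e$participant_id, mean)
    grp_of_subj <- tapply(e$group, e$participant_id, `[`, 1)
    ss_between <- 2 * sum((subj - grand)^2)
    g_means <- tapply(y, e$group, mean)
    n_g <- table(grp_of_subj)
    ss_group <- sum(2 * n_g * (g_means[names(n_g)] - grand)^2)
    ss_subj_w <- ss_between - ss_group
    c_means <- tapply(y, e$condition, mean)
    ss_cond <- sum(2 * n * (c_means - grand)^2)
    cell_means <- tapply(y, list(e$group, e$condition), mean)
    ss_cells <- n * sum((cell_means - grand)^2)
    ss_int <- ss_cells - ss_group - ss_cond
    ss_total <- sum((y - grand)^2)
    ss_resid <- ss_total - ss_between - ss_cond - ss_int
    df_err_b <- 2 * n - 2
    f_group <- (ss_group / 1) / (ss_subj_w / df_err_b)
    f_cond <- (ss_cond / 1) / (ss_resid / df_err_b)
    f_int <- (ss_int / 1) / (ss_resid / df_err_b)
    expect_equal(got$statistic, c(f_group, f_cond, f_int), tolerance = 1e-8)
    expect_equal(got$df_error, rep(df_err_b, 3))
    expect_equal(got$p.value,
                 pf(c(f_group, f_cond, f_int), 1, df_err_b, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("empirical power of the group test matches the analytic oracle", {
  # random intercept SD 1, residual SD 1, group shift 1.2, n = 12 per group:
  # the group F-test equals a two-sample t-test on subject means, whose
  # power is available in closed form
  n <- 12; delta <- 1.2
  oracle <- stats::power.t.test(n = n, delta = delta,
                                sd = sqrt(1 + 1 / 2))$power
  reps <- 400
  hits <- withr::with_seed(77, {
    sum(replicate(reps, {
      b <- rnorm(2 * n)
      shift <- rep(c(0, delta), each = n)
      e <- est_table(b + shift + rnorm(2 * n), b + shift + rnorm(2 * n),
                     group = rep(c("control", "gambler"), each = n))
      a <- group_condition_anova(e)
      a$p.value[a$effect == "group"] < 0.05
    }))
  })
  se <- sqrt(oracle * (1 - oracle) / reps)
  expect_lt(abs(hits / reps - oracle), 3 * se)
})

test_that("severity correlation is one-sided for a positive association in gamblers", {
  tab <- tibble::tibble(group = "gambler",
                        log_k_control = c(-5, -4, -3, -2),
                        severity = c(0, 1, 2, 3))
  r <- severity_correlation(tab)
  expect_equal(r$estimate, 1)
  anti <- dplyr::mutate(tab, severity = rev(severity))
  r2 <- severity_correlation(anti)
  expect_equal(r2$estimate, -1)
  expect_gt(r2$p.value, 0.99)
  expect_error(severity_correlation(dplyr::mutate(tab, severity = 1)),
               class = "discountr_validation_error")
  expect_error(severity_correlation(tab[1:2, ]),
               class = "discountr_validation_error")
  # only gambler rows count
  with_controls <- dplyr::bind_rows(tab,
    tibble::tibble(group = "control", log_k_control = rnorm(4), severity = 0))
  expect_equal(severity_correlation(with_controls)$n, 4)
})

test_that("a planted regression coefficient on baseline log(k) is recovered", {
  set.seed(9)
  n <- 40
  tab <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    group = rep(c("control", "gambler"), each = n / 2),
    log_k_control = rnorm(n, -4, 1.2),
    age = rnorm(n, 30, 8), education = rnorm(n, 11, 1.5),
    income = rnorm(n, 1200, 500), ftnd = rnorm(n, 3, 2),
    audit = rnorm(n, 8, 4), bdi = rnorm(n, 8, 5),
    imagery = rnorm(n, 3, 1), severity = rnorm(n))
  tab$tag_effect <- 0.14 * tab$log_k_control # zero-noise plant
  fit <- suppressWarnings(tag_effect_regression(tab))
  b <- fit$estimate[fit$term == "log_k_control"]
  expect_equal(b, 0.14, tolerance = 1e-8)
  expect_true("bdi:severity" %in% fit$term)
  # with noise the recovery is within 3 standard errors
  tab$tag_effect <- 0.14 * tab$log_k_control + rnorm(n, sd = 0.2)
  fit2 <- tag_effect_regression(tab)
  i <- fit2$term == "log_k_control"
  expect_lt(abs(fit2$estimate[i] - 0.14), 3 * fit2$std.error[i])
})

test_that("regression degenerate cases: intercept-only mean, collinearity, constants", {
  tab <- tibble::tibble(participant_id = paste0("p", 1:10),
                        tag_effect = rnorm(10, 0.3))
  fit <- tag_effect_regression(tab, tag_effect ~ 1)
  expect_equal(fit$estimate, mean(tab$tag_effect))
  # duplicated predictor column
  tab2 <- dplyr::mutate(tab, x = rnorm(10), x2 = x)
  expect_error(tag_effect_regression(tab2, tag_effect ~ x + x2),
               "collinear", class = "discountr_validation_error")
  # all-zero predictors collapse to the intercept-only fit
  tab3 <- dplyr::mutate(tab, z1 = 0, z2 = 0)
  expect_warning(fit3 <- tag_effect_regression(tab3, tag_effect ~ z1 + z2),
                 "constant predictor")
  expect_equal(fit3$estimate, mean(tab$tag_effect))
  # more predictors than rows
  tab4 <- tibble::tibble(tag_effect = rnorm(3), a = rnorm(3), b = rnorm(3),
                         c = rnorm(3))
  expect_error(tag_effect_regression(tab4, tag_effect ~ a + b + c),
               class = "discountr_validation_error")
})

test_that("the 2x2 proportion test matches the textbook chi-square and is symmetric", {
  same <- proportion_comparison(10, 20, 10, 20)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # the study's counts: 19/31 gamblers vs 18/32 controls improved
  got <- proportion_comparison(19, 31, 18, 32, correct = TRUE)
  # independent route: Yates-corrected chi-square from the 2x2 table
  o <- matrix(c(19, 31 - 19, 18, 32 - 18), 2, byrow = TRUE)
  tot <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / tot
  chi <- sum((abs(o - e) - 0.5)^2 / e)
  expect_equal(got$statistic, chi, tolerance = 1e-10)
  expect_equal(got$p.value, pchisq(chi, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  swapped <- proportion_comparison(18, 32, 19, 31)
  expect_equal(swapped$statistic, got$statistic)
  # uncorrected variant matches the raw chi-square
  raw <- proportion_comparison(19, 31, 18, 32, correct = FALSE)
  chi_raw <- sum((o - e)^2 / e)
  expect_equal(raw$statistic, chi_raw, tolerance = 1e-10)
  expect_error(proportion_comparison(0, 0, 1, 2),
               class = "discountr_validation_error")
  expect_error(proportion_comparison(5, 3, 1, 2),
               class = "discountr_validation_error")
})

test_that("participant tables join estimates with covariates", {
  e <- est_table(c(-4, -3.6, -4.4, -3), c(-4.2, -3.9, -4.4, -3.4))
  e$log_beta <- rnorm(8)
  cov <- tibble::tibble(participant_id = sprintf("p%02d", 1:4),
                        severity = c(0.2, -1, 0.5, 2))
  tab <- participant_table(e, cov)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("log_k_control", "log_k_episodic", "tag_effect",
                    "log_beta_control", "severity") %in% names(tab)))
  expect_equal(tab$tag_effect, tab$log_k_control - tab$log_k_episodic)
})

test_that("demographic comparisons use Welch degrees of freedom", {
  set.seed(4)
  tab <- tibble::tibble(group = rep(c("control", "gambler"), c(20, 14)),
                        age = c(rnorm(20, 28, 7), rnorm(14, 30, 11)),
                        income = c(rnorm(20, 1100, 600), rnorm(14, 1300, 700)))
  out <- compare_demographics(tab)
  expect_equal(out$variable, c("age", "income"))
  ref <- t.test(age ~ group, data = tab)
  expect_equal(out$statistic[1], unname(ref$statistic))
  expect_equal(out$df[1], unname(ref$parameter))
  expect_false(out$df[1] == 32) # fractional, not pooled
  expect_error(compare_demographics(dplyr::mutate(tab, group = "x")),
               class = "discountr_validation_error")
})
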