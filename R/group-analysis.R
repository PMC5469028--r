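#' Per-participant episodic tag-effect
#'
#' The tag-effect quantifies how much episodic future-event tags reduce
#' discounting: the difference of log(k) estimates between conditions,
#' `log(k)` control minus `log(k)` episodic. Positive values mean the
#' participant discounted less steeply (was less impulsive) under episodic
#' tags.
#'
#' @param estimates A long parameter table as produced by
#'   [point_estimates()]: columns `participant_id`, `group`, `condition`,
#'   `log_k` with one row per participant x condition.
#' @return A tibble with `participant_id`, `group`, `tag_effect`.
#' @export
tag_effect <- function(estimates) {
  wide <- pivot_estimates(estimates, "log_k")
  dplyr::transmute(wide, .data$participant_id, .data$group,
                   tag_effect = .data$log_k_control - .data$log_k_episodic)
}

# long estimates -> wide, erroring on missing cells
pivot_estimates <- function(estimates, parameter) {
  estimates <- tibble::as_tibble(estimates)
  needed <- c("participant_id", "group", "condition", parameter)
  if (!all(needed %in% names(estimates))) {
    abort(paste0("Estimates table needs columns: ",
                 paste(needed, collapse = ", ")),
          class = "discountr_validation_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(estimates, dplyr::all_of(needed)),
    names_from = "condition", values_from = dplyr::all_of(parameter),
    names_prefix = paste0(parameter, "_"))
  both <- paste0(parameter, "_", c("control", "episodic"))
  if (!all(both %in% names(wide)) || anyNA(wide[both])) {
    abort("Every participant needs estimates in both conditions.",
          class = "discountr_validation_error")
  }
  wide
}

#' Assemble a per-participant analysis table
#'
#' Joins the condition-wise parameter estimates (widened to one row per
#' participant, with the tag-effect precomputed) to an optional covariate
#' table keyed by `participant_id`.
#'
#' @param estimates Long estimates from [point_estimates()].
#' @param covariates Optional per-participant covariate table
#'   (`participant_id` plus e.g. `age`, `education`, `income`, `ftnd`,
#'   `audit`, `bdi`, `imagery`, `severity`).
#' @return A tibble, one row per participant.
#' @export
participant_table <- function(estimates, covariates = NULL) {
  wide_k <- pivot_estimates(estimates, "log_k")
  out <- dplyr::left_join(wide_k, tag_effect(estimates),
                          by = c("participant_id", "group"))
  if ("log_beta" %in% names(estimates)) {
    wide_b <- pivot_estimates(estimates, "log_beta")
    out <- dplyr::left_join(out, dplyr::select(wide_b, -"group"),
                            by = "participant_id")
  }
  if (!is.null(covariates)) {
    out <- dplyr::left_join(out, tibble::as_tibble(covariates),
                            by = "participant_id")
  }
  out
}

#' Composite addiction-severity score
#'
#' Aggregates the two gambling instruments by averaging within-cohort
#' z-scores, yielding a single severity score per participant. Location
#' and scale of either raw instrument cancel, so the score is invariant to
#' affine rescaling of the inputs.
#'
#' @param kfg,sogs Raw instrument scores for the scored participants.
#' @param kfg_ref,sogs_ref Cohort vectors defining the z-scaling (default:
#'   the scored vectors themselves).
#' @return Numeric vector of composite scores.
#' @export
severity_score <- function(kfg, sogs, kfg_ref = kfg, sogs_ref = sogs) {
  if (sd(kfg_ref) == 0 || sd(sogs_ref) == 0) {
    abort("Reference cohorts must have positive variance.",
          class = "discountr_validation_error")
  }
  z1 <- (kfg - mean(kfg_ref)) / sd(kfg_ref)
  z2 <- (sogs - mean(sogs_ref)) / sd(sogs_ref)
  (z1 + z2) / 2
}

#' Mixed-design group-by-condition ANOVA on a fitted parameter
#'
#' The behavioural headline test: a two-way analysis of the
#' log-transformed parameter with group (gamblers vs. controls) as the
#' between-participant factor and condition (episodic vs. control) as the
#' within-participant factor, participant as the blocking unit. Implemented
#' through `stats::aov()` with an `Error(participant)` stratum, which
#' performs the standard mixed-design partitioning.
#'
#' @param estimates Long estimates table ([point_estimates()] output).
#' @param parameter Column to analyse (`"log_k"` or `"log_beta"`).
#' @return A tibble with one row per effect (`group`, `condition`,
#'   `group:condition`): `df`, `df_error`, `statistic` (F), `p.value`. An
#'   effect with an exactly zero sum of squares reports F = 0, p = 1.
#' @export
group_condition_anova <- function(estimates, parameter = "log_k") {
  wide <- pivot_estimates(estimates, parameter) # validates complete cells
  if (any(table(wide$group) < 2) || dplyr::n_distinct(wide$group) < 2) {
    abort("Need >= 2 participants in each of two groups.",
          class = "discountr_validation_error")
  }
  long <- dplyr::mutate(
    dplyr::select(estimates, "participant_id", "group", "condition",
                  value = dplyr::all_of(parameter)),
    participant_id = factor(.data$participant_id),
    group = factor(.data$group), condition = factor(.data$condition))
  fit <- aov(value ~ group * condition + Error(participant_id),
             data = long)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant_id"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  # degenerate inputs: an effect whose sum of squares is zero (to floating
  # point, relative to the total SS of the response) is reported as F = 0,
  # p = 1 even when the error sum of squares is also zero, where the raw
  # ratio would be 0/0 noise
  ss_floor <- 1e-12 * max(sum((long$value - mean(long$value))^2), 1)
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    err <- trimws(rownames(tab)) == "Residuals"
    f <- tab$`F value`[i]
    p <- tab$`Pr(>F)`[i]
    if (tab$`Sum Sq`[i] <= ss_floor) {
      f <- 0
      p <- 1
    }
    tibble::tibble(effect = name, df = tab$Df[i], df_error = tab$Df[err],
                   statistic = f, p.value = p)
  }
  dplyr::bind_rows(row_of(between, "group"),
                   row_of(within, "condition"),
                   row_of(within, "group:condition"))
}

#' Correlation of baseline discounting with addiction severity
#'
#' Pearson correlation, within the gambler group, between the
#' control-condition log(k) and the composite severity score, with a
#' one-sided p-value for a positive association (steeper baseline
#' discounting in more severe gambling).
#'
#' @param table A [participant_table()] with columns `group`,
#'   `log_k_control` and `severity`.
#' @return A one-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p.value` (one-sided), `n`.
#' @export
severity_correlation <- function(table) {
  g <- table[table$group == "gambler", , drop = FALSE]
  g <- g[complete.cases(g[c("log_k_control", "severity")]), , drop = FALSE]
  if (nrow(g) < 3) {
    abort("Need >= 3 gambler rows with severity scores.",
          class = "discountr_validation_error")
  }
  if (sd(g$log_k_control) == 0 || sd(g$severity) == 0) {
    abort("Constant vectors: correlation undefined.",
          class = "discountr_validation_error")
  }
  ct <- stats::cor.test(g$log_k_control, g$severity,
                        alternative = "greater", method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 n = nrow(g))
}

#' Multiple regression on the tag-effect
#'
#' Ordinary least squares of the per-participant tag-effect on the study's
#' predictor set — group, age, education (school years), income, nicotine
#' dependence (FTND), alcohol use (AUDIT), depression (BDI), post-test
#' imagery score and control-condition log(k) — plus the severity-by-BDI
#' interaction. Predictors absent from the table are dropped from the
#' default formula and constant predictors are dropped with a warning; a
#' custom formula overrides the default. A rank-deficient design is an
#' error naming the collinear columns.
#'
#' @param table A [participant_table()] (or any data frame) containing
#'   `tag_effect` and the predictors.
#' @param formula Optional model formula; default uses every standard
#'   predictor present in `table`.
#' @return A tibble of coefficients: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tag_effect_regression <- function(table, formula = NULL) {
  table <- tibble::as_tibble(table)
  if (is.null(formula)) {
    base_preds <- c("group", "age", "education", "income", "ftnd", "audit",
                    "bdi", "imagery", "log_k_control")
    preds <- intersect(base_preds, names(table))
    if (all(c("severity", "bdi") %in% names(table))) {
      preds <- c(preds, "severity", "severity:bdi")
    }
    if (!length(preds)) preds <- "1"
    formula <- stats::reformulate(preds, response = "tag_effect")
  }
  table <- table[complete.cases(table[all.vars(formula)]), , drop = FALSE]
  # constant predictors carry no information and would only trip the rank
  # check; drop them (the intercept absorbs them) with a warning
  num_preds <- intersect(all.vars(formula)[-1], names(table))
  const <- num_preds[purrr::map_lgl(table[num_preds],
                                    ~ dplyr::n_distinct(.x) == 1)]
  if (length(const)) {
    warn(paste0("Dropping constant predictor(s): ",
                paste(const, collapse = ", ")))
    keep <- setdiff(all.vars(formula)[-1], const)
    terms_keep <- attr(stats::terms(formula), "term.labels")
    terms_keep <- terms_keep[!purrr::map_lgl(
      strsplit(terms_keep, ":"), ~ any(.x %in% const))]
    formula <- if (length(terms_keep)) {
      stats::reformulate(terms_keep, response = "tag_effect")
    } else {
      tag_effect ~ 1
    }
  }
  mm <- model.matrix(formula, data = table)
  if (nrow(mm) <= ncol(mm)) {
    abort("Need more participants than predictors.",
          class = "discountr_validation_error")
  }
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "discountr_validation_error")
  }
  fit <- lm(formula, data = table)
  cf <- summary(fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p.value = unname(cf[, 4]))
}

#' Compare the proportion of participants improved by episodic tags
#'
#' Chi-square test of equal proportions in a 2x2 table (participants with
#' a lower discount rate in the episodic condition, per group). Yates'
#' continuity correction is applied by default and is configurable.
#'
#' @param improved_a,n_a Improved count and total in group A.
#' @param improved_b,n_b Improved count and total in group B.
#' @param correct Apply the continuity correction?
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p.value`,
#'   `prop_a`, `prop_b`, `correct`.
#' @export
proportion_comparison <- function(improved_a, n_a, improved_b, n_b,
                                  correct = TRUE) {
  counts <- c(improved_a, n_a, improved_b, n_b)
  if (any(counts < 0) || improved_a > n_a || improved_b > n_b ||
      n_a == 0 || n_b == 0) {
    abort("Counts must be nonnegative with improved <= total and totals > 0.",
          class = "discountr_validation_error")
  }
  pt <- suppressWarnings(
    stats::prop.test(c(improved_a, improved_b), c(n_a, n_b),
                     correct = correct))
  tibble::tibble(statistic = unname(pt$statistic),
                 df = unname(pt$parameter), p.value = pt$p.value,
                 prop_a = improved_a / n_a, prop_b = improved_b / n_b,
                 correct = correct)
}

#' Plot condition means of a fitted parameter by group
#'
#' Group-by-condition means of log(k) (or another parameter) with
#' standard-error bars — the standard behavioural summary figure.
#'
#' @param estimates Long estimates table.
#' @param parameter Column to summarise.
#' @return A ggplot object.
#' @export
plot_group_condition <- function(estimates, parameter = "log_k") {
  summ <- dplyr::summarise(
    dplyr::group_by(estimates, .data$group, .data$condition),
    mean = mean(.data[[parameter]]),
    se = sd(.data[[parameter]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.05,
                           position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::labs(x = "Condition", y = paste("Mean", parameter),
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Discount-function curves
#'
#' Subjective value of a 100-euro reward as a function of delay for a set
#' of discount rates, under any of the three value-based models.
#'
#' @param k Vector of discount rates to draw.
#' @param model Value-based model name.
#' @param amount Reward magnitude, euros.
#' @param max_delay Largest delay drawn, days.
#' @param s Sensitivity exponent (constant-sensitivity model).
#' @return A ggplot object.
#' @export
plot_discount_curves <- function(k, model = "hyperbolic", amount = 100,
                                 max_delay = 200, s = 1) {
  model <- match.arg(model, TD_MODELS[1:3])
  grid <- tidyr::expand_grid(k = k, delay = seq(0, max_delay, length.out = 201))
  grid$sv <- switch(model,
    hyperbolic = sv_hyperbolic(amount, grid$delay, grid$k),
    exponential = sv_exponential(amount, grid$delay, grid$k),
    constant_sensitivity = sv_constant_sensitivity(amount, grid$delay,
                                                   grid$k, s))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$delay, y = .data$sv,
                                     colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Delay (days)", y = "Subjective value (euros)",
                  colour = "k (per day)") +
    ggplot2::theme_minimal()
}

#' Welch comparisons of demographic and clinical covariates between groups
#'
#' Per-variable two-sample t-tests with the Welch unequal-variance degrees
#' of freedom, the standard reporting for matched-sample demographic
#' tables.
#'
#' @param table Per-participant data frame with a `group` column (two
#'   levels) and the covariates to compare.
#' @param vars Character vector of numeric columns to compare; defaults to
#'   every numeric column.
#' @return A tibble with one row per variable: group means and SDs,
#'   `statistic` (t), `df` (fractional, Welch), `p.value`.
#' @export
compare_demographics <- function(table, vars = NULL) {
  table <- tibble::as_tibble(table)
  groups <- sort(unique(table$group))
  if (length(groups) != 2) {
    abort("`table$group` must have exactly two levels.",
          class = "discountr_validation_error")
  }
  if (is.null(vars)) {
    vars <- names(table)[purrr::map_lgl(table, is.numeric)]
  }
  purrr::map_dfr(vars, function(v) {
    x <- table[[v]][table$group == groups[1]]
    y <- table[[v]][table$group == groups[2]]
    tt <- stats::t.test(x, y) # Welch by default
    tibble::tibble(variable = v,
                   mean_1 = mean(x), sd_1 = sd(x),
                   mean_2 = mean(y), sd_2 = sd(y),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value)
  })
}
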