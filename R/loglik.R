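# Parameter tables pair each participant x condition with the free
# parameters of one model:
#   value models: log_k, log_beta (constant_sensitivity additionally s)
#   itch:         the five ITCH_WEIGHTS columns
# This is the exact shape point_estimates() emits and simulate_cohort()
# records as truth.

params_cols <- function(model) {
  switch(model,
    hyperbolic = c("log_k", "log_beta"),
    exponential = c("log_k", "log_beta"),
    constant_sensitivity = c("log_k", "s", "log_beta"),
    itch = ITCH_WEIGHTS,
    abort(paste0("Unknown model: ", model), class = "discountr_domain_error")
  )
}

# join trials to their participant x condition parameter rows; error if any
# trial has no parameters
join_params <- function(trials, params, model) {
  needed <- params_cols(model)
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols)) {
    abort(paste0("Parameter table lacks column(s) required by the ", model,
                 " model: ", paste(missing_cols, collapse = ", ")),
          class = "discountr_lookup_error")
  }
  joined <- dplyr::left_join(
    trials,
    dplyr::select(params, dplyr::all_of(c("participant_id", "condition", needed))),
    by = c("participant_id", "condition")
  )
  bad <- !complete.cases(joined[needed])
  if (any(bad)) {
    who <- unique(paste(joined$participant_id[bad], joined$condition[bad], sep = "/"))
    abort(paste0("No parameters for participant/condition: ",
                 paste(utils::head(who, 5), collapse = ", ")),
          class = "discountr_lookup_error")
  }
  joined
}

#' Per-trial choice probabilities under a fitted or assumed model
#'
#' Computes, for every trial, the probability of choosing the larger-later
#' option given each participant's condition-specific parameters. Value-based
#' models (`hyperbolic`, `exponential`, `constant_sensitivity`) combine the
#' model's subjective value with the softmax rule; `itch` applies its own
#' logistic rule directly.
#'
#' @param trials A trial table (see [validate_trials()]); `choice_ll` not
#'   required.
#' @param params A parameter table with one row per participant x condition:
#'   columns `participant_id`, `condition`, and the model's parameters
#'   (`log_k`, `log_beta`, plus `s` for constant sensitivity, or the five
#'   ITCH weight columns).
#' @param model One of `"hyperbolic"`, `"exponential"`,
#'   `"constant_sensitivity"`, `"itch"`.
#' @param ss_amount Fixed smaller-sooner amount, euros.
#' @return The trials tibble with a `p_ll` column appended.
#' @export
choice_prob <- function(trials, params, model = "hyperbolic", ss_amount = 20) {
  model <- match.arg(model, TD_MODELS)
  trials <- validate_trials(trials, require_choice = FALSE,
                            ss_amount = ss_amount, allow_dominated = TRUE)
  joined <- join_params(trials, params, model)
  p <- switch(model,
    hyperbolic = p_choose_ll_softmax(
      sv_hyperbolic(joined$amount_ll, joined$delay_days, exp(joined$log_k)),
      ss_amount, exp(joined$log_beta)),
    exponential = p_choose_ll_softmax(
      sv_exponential(joined$amount_ll, joined$delay_days, exp(joined$log_k)),
      ss_amount, exp(joined$log_beta)),
    constant_sensitivity = p_choose_ll_softmax(
      sv_constant_sensitivity(joined$amount_ll, joined$delay_days,
                              exp(joined$log_k), joined$s),
      ss_amount, exp(joined$log_beta)),
    itch = plogis(itch_logit(joined$amount_ll, joined$delay_days,
                             ss_amount, 0,
                             as.list(joined[ITCH_WEIGHTS])))
  )
  trials$p_ll <- as.numeric(p)
  trials
}

# probabilities are clamped before taking logs so the pointwise
# log-likelihood stays finite under extreme parameter draws
P_FLOOR <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, P_FLOOR), 1 - P_FLOOR)

#' Pointwise Bernoulli log-likelihood of observed choices
#'
#' One log-likelihood per trial of the observed binary choice under the
#' model's choice probability — one column of the trials-by-samples matrix
#' that drives WAIC. Probabilities are clamped to `[1e-12, 1 - 1e-12]`
#' before the log so the result is finite for any valid parameters.
#'
#' @inheritParams choice_prob
#' @param trials A trial table including `choice_ll`.
#' @return Numeric vector, one finite log-likelihood per trial, in trial
#'   order.
#' @export
pointwise_loglik <- function(trials, params, model = "hyperbolic",
                             ss_amount = 20) {
  trials <- validate_trials(trials, ss_amount = ss_amount,
                            allow_dominated = TRUE)
  with_p <- choice_prob(trials, params, model = model, ss_amount = ss_amount)
  p <- clamp_prob(with_p$p_ll)
  ifelse(trials$choice_ll == 1, log(p), log1p(-p))
}
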