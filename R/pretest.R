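# negative log-likelihood of one participant-condition cell's choices under
# a value-based model, parameterised on the log scale
cell_negll <- function(theta, trials, model, ss_amount) {
  params <- tibble::tibble(
    participant_id = trials$participant_id[1],
    condition = trials$condition[1],
    log_k = theta[["log_k"]],
    log_beta = theta[["log_beta"]]
  )
  if (model == "constant_sensitivity") params$s <- exp(theta[["log_s"]])
  -sum(pointwise_loglik(trials, params, model = model, ss_amount = ss_amount))
}

#' Independent per-cell maximum-likelihood fits
#'
#' Fits each participant-by-condition cell separately by maximising the
#' Bernoulli likelihood over `log(k)` and `log(beta)` (plus `log(s)` for the
#' constant-sensitivity model) with box constraints. No pooling: this is the
#' unshrunk baseline the hierarchical fit is compared against, and the
#' engine behind [pretest_estimate()].
#'
#' @param trials A trial table including `choice_ll`.
#' @param model One of the value-based models (`"hyperbolic"`,
#'   `"exponential"`, `"constant_sensitivity"`).
#' @param ss_amount Immediate amount, euros.
#' @param log_k_bounds,log_beta_bounds Box constraints for the optimiser.
#' @return A parameter tibble (`participant_id`, `condition`, `log_k`,
#'   `log_beta`, `s` where applicable, `negll`).
#' @export
fit_mle <- function(trials, model = "hyperbolic", ss_amount = 20,
                    log_k_bounds = log(c(1e-5, 2)),
                    log_beta_bounds = log(c(1e-2, 100))) {
  model <- match.arg(model, TD_MODELS[1:3])
  trials <- validate_trials(trials, ss_amount = ss_amount,
                            allow_dominated = TRUE)
  cells <- dplyr::group_split(dplyr::group_by(trials, .data$participant_id,
                                              .data$condition))
  purrr::map_dfr(cells, function(cell) {
    start <- c(log_k = -4, log_beta = 0.5)
    lower <- c(log_k_bounds[1], log_beta_bounds[1])
    upper <- c(log_k_bounds[2], log_beta_bounds[2])
    if (model == "constant_sensitivity") {
      start <- c(start, log_s = 0)
      lower <- c(lower, log(0.1)); upper <- c(upper, log(10))
    }
    fit <- optim(start, cell_negll, trials = cell, model = model,
                 ss_amount = ss_amount, method = "L-BFGS-B",
                 lower = lower, upper = upper)
    out <- tibble::tibble(
      participant_id = cell$participant_id[1],
      condition = cell$condition[1],
      log_k = fit$par[["log_k"]],
      log_beta = fit$par[["log_beta"]],
      negll = fit$value
    )
    if (model == "constant_sensitivity") out$s <- exp(fit$par[["log_s"]])
    out
  })
}

#' Estimate a pretest discount rate for one participant
#'
#' Reduces a single participant's pretest choices to one hyperbolic discount
#' rate `k` by per-participant maximum likelihood (no hierarchy). A
#' degenerate response pattern — every choice the immediate option, or every
#' choice the delayed option — carries no information about `k` beyond a
#' bound, so the estimate is clamped to the configured limits with a
#' warning: an always-delayed responder is assigned the lower clamp
#' (shallowest admissible discounting), an always-immediate responder the
#' upper clamp.
#'
#' @param trials Pretest trial table for exactly one participant.
#' @param k_bounds Admissible range for `k` (per day).
#' @param ss_amount Immediate amount, euros.
#' @return A single `k` (rate per day), with attribute `clamped` flagging a
#'   degenerate pattern.
#' @export
pretest_estimate <- function(trials, k_bounds = c(1e-5, 2), ss_amount = 20) {
  trials <- validate_trials(trials, ss_amount = ss_amount,
                            allow_dominated = TRUE)
  if (dplyr::n_distinct(trials$participant_id) != 1) {
    abort("Pretest estimation expects exactly one participant.",
          class = "discountr_validation_error")
  }
  if (all(trials$choice_ll == 1)) {
    warn("All choices were the delayed option; k clamped to the lower bound.")
    return(structure(k_bounds[1], clamped = TRUE))
  }
  if (all(trials$choice_ll == 0)) {
    warn("All choices were the immediate option; k clamped to the upper bound.")
    return(structure(k_bounds[2], clamped = TRUE))
  }
  trials$condition <- trials$condition[1] # single cell: pool all pretest trials
  est <- fit_mle(trials, model = "hyperbolic", ss_amount = ss_amount,
                 log_k_bounds = log(k_bounds))
  structure(exp(est$log_k[1]), clamped = FALSE)
}

#' Simulate an adaptive pretest session
#'
#' Runs a per-delay bisection staircase on the larger-later amount against a
#' simulated responder with known hyperbolic parameters: at each step the
#' offered amount is the midpoint of the current bracket, the response is
#' drawn from the softmax rule, and the bracket halves toward the
#' indifference amount (a delayed choice lowers the upper edge, an immediate
#' choice raises the lower edge). The recorded choices are suitable input
#' for [pretest_estimate()].
#'
#' @param k,beta True hyperbolic discount rate (per day) and softmax
#'   temperature (euros) of the simulated responder.
#' @param delays Delays (days) staircased over.
#' @param steps Bisection steps per delay.
#' @param amount_range Initial amount bracket, euros.
#' @param ss_amount Immediate amount, euros.
#' @param seed Optional integer seed.
#' @param participant_id Identifier written into the output table.
#' @return A pretest trial table (`participant_id`, `group`, `condition`,
#'   `amount_ll`, `delay_days`, `choice_ll`).
#' @export
simulate_pretest <- function(k, beta, delays = c(7, 14, 30, 60, 120, 180),
                             steps = 10, amount_range = c(20.5, 200),
                             ss_amount = 20, seed = NULL,
                             participant_id = "pretest") {
  run <- function() {
    purrr::map_dfr(delays, function(d) {
      lo <- amount_range[1]; hi <- amount_range[2]
      purrr::map_dfr(seq_len(steps), function(i) {
        a <- (lo + hi) / 2
        p <- p_choose_ll_softmax(sv_hyperbolic(a, d, k), ss_amount, beta)
        y <- rbinom(1, 1, p)
        if (y == 1) hi <<- a else lo <<- a
        tibble::tibble(participant_id = participant_id, group = "none",
                       condition = "control", amount_ll = a,
                       delay_days = d, choice_ll = y)
      })
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
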