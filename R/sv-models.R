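#' Valuation models for intertemporal choice
#'
#' Subjective (discounted) value of a delayed reward under the three
#' value-based candidate models. All three return the undiscounted amount at
#' delay zero and decrease strictly in both delay and discount rate.
#'
#' * `sv_hyperbolic()`: \eqn{SV = A / (1 + kD)} — hyperbolic discounting with
#'   a single discount rate `k` per day; larger `k` means steeper discounting
#'   (higher impulsivity).
#' * `sv_exponential()`: \eqn{SV = A \exp(-kD)} — classical discounted
#'   utility with a constant per-day discount rate.
#' * `sv_constant_sensitivity()`: \eqn{SV = A \exp(-(kD)^s)} — adds a time
#'   sensitivity exponent `s`; reduces exactly to the exponential model at
#'   `s = 1`.
#'
#' @param amount Reward magnitude in euros (> 0). Vectorised.
#' @param delay Delay until receipt, in days (>= 0). Vectorised.
#' @param k Discount rate per day (> 0).
#' @param s Time-sensitivity exponent (> 0, constant-sensitivity model only).
#'
#' @return Numeric vector of subjective values in euros.
#' @examples
#' sv_hyperbolic(40, 100, k = 0.01)   # 20: value halves when kD = 1
#' sv_exponential(40, 0, k = 0.05)    # 40: no discounting at delay zero
#' sv_constant_sensitivity(40, 30, k = 0.02, s = 1) # == sv_exponential
#' @export
sv_hyperbolic <- function(amount, delay, k) {
  check_sv_args(amount, delay, k)
  amount / (1 + k * delay)
}

#' @rdname sv_hyperbolic
#' @export
sv_exponential <- function(amount, delay, k) {
  check_sv_args(amount, delay, k)
  amount * exp(-k * delay)
}

#' @rdname sv_hyperbolic
#' @export
sv_constant_sensitivity <- function(amount, delay, k, s) {
  check_sv_args(amount, delay, k)
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("`s` must be finite and > 0.", class = "discountr_domain_error")
  }
  amount * exp(-(k * delay)^s)
}

check_sv_args <- function(amount, delay, k) {
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    abort("`amount` must be finite and > 0.", class = "discountr_domain_error")
  }
  if (any(!is.finite(delay)) || any(delay < 0)) {
    abort("`delay` must be finite and >= 0.", class = "discountr_domain_error")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be finite and > 0.", class = "discountr_domain_error")
  }
  invisible(NULL)
}

#' Softmax choice probability for the larger-later option
#'
#' Transforms the subjective values of the two options into the probability
#' of choosing the larger-later (LL) reward,
#' \eqn{p_{LL} = \exp(SV_{LL}/\beta) / (\exp(SV_{SS}/\beta) +
#' \exp(SV_{LL}/\beta))}, with temperature \eqn{\beta} (in euros) governing
#' decision noise. Computed as the logistic of the value difference scaled by
#' \eqn{\beta}, which is algebraically identical but does not overflow for
#' small \eqn{\beta}.
#'
#' @param sv_ll Subjective value of the larger-later option, euros.
#' @param sv_ss Subjective value of the smaller-sooner option, euros
#'   (the study design fixes the SS offer at 20 euros immediately).
#' @param beta Softmax temperature in euros (> 0). Larger values give noisier,
#'   more random choice; as `beta` shrinks the rule approaches strict
#'   maximisation.
#'
#' @return Probability of choosing the LL option, in (0, 1).
#' @examples
#' p_choose_ll_softmax(20, 20, beta = 3)           # 0.5 at indifference
#' p_choose_ll_softmax(20 + 2 * log(3), 20, 2)     # 0.75
#' @export
p_choose_ll_softmax <- function(sv_ll, sv_ss, beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    abort("`beta` must be finite and > 0.", class = "discountr_domain_error")
  }
  plogis((sv_ll - sv_ss) / beta)
}

#' Intertemporal choice heuristic (ITCH) choice probability
#'
#' A logistic choice rule on absolute and relative differences between the
#' two options' amounts and delays, rather than on discounted values:
#' \deqn{p_{LL} = logit^{-1}(\beta_1 + \beta_{xA}(x_2 - x_1) +
#'   \beta_{xR}(x_2 - x_1)/\bar x + \beta_{tA}(t_2 - t_1) +
#'   \beta_{tR}(t_2 - t_1)/\bar t)}
#' where option 2 is larger-later, option 1 smaller-sooner, and
#' \eqn{\bar x,\bar t} are the within-trial means of the two amounts and the
#' two delays. When both delays are equal (including both zero) the relative
#' delay term is defined as zero.
#'
#' @param amount_ll,delay_ll Larger-later amount (euros) and delay (days).
#' @param amount_ss,delay_ss Smaller-sooner amount and delay; defaults match
#'   the study design (20 euros, immediately).
#' @param weights Named numeric vector or one-row data frame with elements
#'   `b_intercept`, `b_amount_abs`, `b_amount_rel`, `b_delay_abs`,
#'   `b_delay_rel`.
#'
#' @return Probability of choosing the LL option, in (0, 1).
#' @examples
#' w <- c(b_intercept = 0, b_amount_abs = 0, b_amount_rel = 0,
#'        b_delay_abs = 0, b_delay_rel = 0)
#' p_choose_ll_itch(60, 45, weights = w)  # 0.5: zero logit
#' @export
p_choose_ll_itch <- function(amount_ll, delay_ll, weights,
                             amount_ss = 20, delay_ss = 0) {
  w <- validate_itch_weights(weights)
  x <- itch_logit(amount_ll, delay_ll, amount_ss, delay_ss, w)
  plogis(x)
}

validate_itch_weights <- function(weights) {
  if (is.data.frame(weights)) weights <- unlist(weights[1, , drop = TRUE])
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !all(ITCH_WEIGHTS %in% names(weights)) ||
      any(!is.finite(weights[ITCH_WEIGHTS]))) {
    abort(
      paste0("`weights` must be a named finite numeric vector containing ",
             paste(ITCH_WEIGHTS, collapse = ", "), "."),
      class = "discountr_domain_error"
    )
  }
  weights[ITCH_WEIGHTS]
}

# logit of the ITCH rule; vectorised over offers, scalar weights
itch_logit <- function(amount_ll, delay_ll, amount_ss, delay_ss, w) {
  dx <- amount_ll - amount_ss
  dt <- delay_ll - delay_ss
  xbar <- (amount_ll + amount_ss) / 2
  tbar <- (delay_ll + delay_ss) / 2
  rel_t <- ifelse(dt == 0, 0, dt / tbar)
  w[["b_intercept"]] +
    w[["b_amount_abs"]] * dx +
    w[["b_amount_rel"]] * dx / xbar +
    w[["b_delay_abs"]] * dt +
    w[["b_delay_rel"]] * rel_t
}

#' Indifference amount under hyperbolic discounting
#'
#' The larger-later amount at which a participant with hyperbolic discount
#' rate `k` values the delayed option exactly as much as the immediate
#' smaller-sooner amount: \eqn{A^* = A_{SS}(1 + kD)}, so that
#' `sv_hyperbolic(A*, delay, k) == ss_amount`.
#'
#' @param k Hyperbolic discount rate per day (> 0).
#' @param delay Delay of the larger-later option, days (>= 0).
#' @param ss_amount Immediate amount in euros (study constant 20).
#'
#' @return The indifference amount in euros.
#' @examples
#' indifference_amount(0.01, 45)  # 29: 20 * (1 + 0.45)
#' @export
indifference_amount <- function(k, delay, ss_amount = 20) {
  check_sv_args(ss_amount, delay, k)
  ss_amount * (1 + k * delay)
}
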