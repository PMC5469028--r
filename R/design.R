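#' Configuration for the two-condition trial designer
#'
#' Collects the tunable constants of the episodic discounting task design:
#' total trial count (split evenly between the episodic and control
#' conditions), the fixed immediate amount, the endpoints of the linearly
#' spaced amount half, the standard deviation of the indifference-point
#' tailored amounts, and how control-condition delays are drawn.
#'
#' @param n_trials Total number of trials (even; half per condition).
#' @param ss_amount Fixed immediate smaller-sooner amount, euros.
#' @param linear_range Endpoints of the linearly covered amount range,
#'   euros.
#' @param tailored_sd Standard deviation (euros) of the normal draw around
#'   each trial's indifference amount.
#' @param control_delay_mode `"interleaved"` draws one control delay
#'   uniformly between each pair of consecutive sorted episodic delays and
#'   the remainder uniformly over the full range; `"uniform"` draws all
#'   control delays uniformly between one day and the maximum episodic
#'   delay. Control delays are whole days in either mode.
#' @param truncate If `TRUE` (default), tailored amounts below the linear
#'   minimum are resampled so every offer remains a genuine larger-later
#'   reward.
#' @param seed Optional integer seed; a seeded build is bit-reproducible.
#' @return A list of class `td_design_config`.
#' @export
design_config <- function(n_trials = 80, ss_amount = 20,
                          linear_range = c(20.5, 99.5), tailored_sd = 4,
                          control_delay_mode = c("interleaved", "uniform"),
                          truncate = TRUE, seed = NULL) {
  control_delay_mode <- match.arg(control_delay_mode)
  if (n_trials < 4 || n_trials %% 2 != 0) {
    abort("`n_trials` must be an even number >= 4.",
          class = "discountr_validation_error")
  }
  if (length(linear_range) != 2 || diff(linear_range) <= 0) {
    abort("`linear_range` must be two increasing endpoints.",
          class = "discountr_validation_error")
  }
  if (tailored_sd <= 0 || ss_amount <= 0) {
    abort("`tailored_sd` and `ss_amount` must be > 0.",
          class = "discountr_validation_error")
  }
  structure(list(n_trials = n_trials, ss_amount = ss_amount,
                 linear_range = linear_range, tailored_sd = tailored_sd,
                 control_delay_mode = control_delay_mode,
                 truncate = truncate, seed = seed),
            class = "td_design_config")
}

#' Draw indifference-point tailored larger-later amounts
#'
#' For each delay, draws an amount from a normal distribution centred on the
#' participant's hyperbolic indifference amount at that delay with the
#' configured standard deviation. With `truncate = TRUE`, draws below
#' `min_amount` are resampled; the realised truncation rate is attached as
#' an attribute.
#'
#' @param k Pretest hyperbolic discount rate per day.
#' @param delays Vector of delays in days, one per draw.
#' @param sd Standard deviation of the draw, euros.
#' @param ss_amount Immediate amount, euros.
#' @param min_amount Lower truncation bound, euros.
#' @param truncate Resample draws below `min_amount`?
#' @return Numeric vector of amounts with attribute `truncation_rate` (the
#'   proportion of draws that had to be resampled; 0 when `truncate = FALSE`).
#' @export
draw_tailored_amounts <- function(k, delays, sd = 4, ss_amount = 20,
                                  min_amount = 20.5, truncate = TRUE) {
  mu <- indifference_amount(k, delays, ss_amount)
  x <- rnorm(length(delays), mean = mu, sd = sd)
  n_resampled <- 0L
  if (truncate) {
    below <- which(x < min_amount)
    n_resampled <- length(below)
    guard <- 0L
    while (length(below)) {
      x[below] <- rnorm(length(below), mean = mu[below], sd = sd)
      below <- below[x[below] < min_amount]
      guard <- guard + 1L
      if (guard > 1000L) {
        abort("Tailored-amount truncation failed to converge; indifference points lie far below the admissible range.",
              class = "discountr_validation_error")
      }
    }
  }
  attr(x, "truncation_rate") <- n_resampled / length(delays)
  x
}

# integer control delays: one per gap between consecutive sorted episodic
# delays, remainder uniform over [1, max]; or all uniform
draw_control_delays <- function(n, episodic_delays, mode) {
  dmax <- max(episodic_delays)
  if (mode == "uniform") {
    return(sample.int(dmax, n, replace = TRUE))
  }
  ed <- sort(unique(round(episodic_delays)))
  gaps <- if (length(ed) > 1) {
    purrr::map2_int(ed[-length(ed)], ed[-1],
                    function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1L)
  } else integer(0)
  gaps <- gaps[seq_len(min(length(gaps), n))]
  c(gaps, sample.int(dmax, n - length(gaps), replace = TRUE))
}

#' Build a two-condition trial set from a pretest discount rate and an
#' event list
#'
#' Constructs the full episodic-discounting session for one participant.
#' Within each condition, half of the larger-later amounts form an evenly
#' spaced grid over the configured linear range (20.5–99.5 euros by
#' default) and the other half are drawn around the participant's
#' indifference amount at the trial's delay (normal, SD 4 euros by default,
#' truncated below at the linear minimum). Episodic trials take their delays
#' from the participant's future events, cycled in order, and carry the
#' event's tag; control-condition delays are whole days drawn between one
#' day and the maximum episodic delay (see [design_config()] for the two
#' sampling modes). Trial order is shuffled; with a seed the build is
#' bit-reproducible.
#'
#' @param k Pretest hyperbolic discount rate per day (> 0).
#' @param events Event tibble with columns `label` and `delay_days` (see
#'   [read_events()]).
#' @param config A [design_config()].
#' @return A `td_trialset`: a tibble with columns `trial`, `condition`,
#'   `amount_ll`, `delay_days`, `tag`, `amount_type`, carrying a
#'   `provenance` attribute (pretest `k`, the config, seed, tailored
#'   truncation rate).
#' @export
build_trials <- function(k, events, config = design_config()) {
  if (!is.numeric(k) || k <= 0) {
    abort("`k` must be > 0.", class = "discountr_domain_error")
  }
  events <- validate_events(events)
  stopifnot(inherits(config, "td_design_config"))

  build <- function() {
    n_c <- config$n_trials / 2
    n_lin <- n_c %/% 2
    n_tail <- n_c - n_lin
    grid <- seq(config$linear_range[1], config$linear_range[2],
                length.out = n_lin)
    ep_idx <- rep_len(seq_len(nrow(events)), n_c)
    ep_delays <- events$delay_days[ep_idx]
    ctl_delays <- draw_control_delays(n_c, events$delay_days,
                                      config$control_delay_mode)
    one_condition <- function(condition, delays, tags) {
      tailored <- draw_tailored_amounts(
        k, delays[n_lin + seq_len(n_tail)], sd = config$tailored_sd,
        ss_amount = config$ss_amount, min_amount = config$linear_range[1],
        truncate = config$truncate)
      tibble::tibble(
        condition = condition,
        amount_ll = c(grid, as.numeric(tailored)),
        delay_days = delays,
        tag = tags,
        amount_type = rep(c("linear", "tailored"), c(n_lin, n_tail)),
        .trunc = attr(tailored, "truncation_rate")
      )
    }
    out <- dplyr::bind_rows(
      one_condition("episodic", ep_delays, events$label[ep_idx]),
      one_condition("control", ctl_delays, NA_character_)
    )
    out <- out[sample.int(nrow(out)), ]
    trunc_rate <- mean(out$.trunc)
    out$.trunc <- NULL
    out <- dplyr::mutate(out, trial = dplyr::row_number(), .before = 1)
    structure(out,
              class = c("td_trialset", class(out)),
              provenance = list(k = k, config = config, seed = config$seed,
                                truncation_rate = trunc_rate))
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, build()) else build()
}

#' Check a trial set against the task-design invariants
#'
#' Machine-readable report over a [build_trials()] result: both conditions
#' present and balanced, episodic trials tagged and control trials untagged,
#' all delays at least one day, control delays within the episodic range,
#' linear amounts spanning the configured endpoints exactly, and every
#' amount exceeding the immediate amount (when the build truncated).
#'
#' @param trials A `td_trialset` (or any trial-design tibble with the same
#'   columns).
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
validate_trialset <- function(trials) {
  prov <- attr(trials, "provenance")
  cfg <- prov$config %||% design_config(n_trials = max(4, 2 * (nrow(trials) %/% 2)))
  ep <- trials[trials$condition == "episodic", , drop = FALSE]
  ctl <- trials[trials$condition == "control", , drop = FALSE]
  lin <- trials[trials$amount_type == "linear", , drop = FALSE]
  checks <- list(
    both_conditions_present = list(
      nrow(ep) > 0 && nrow(ctl) > 0,
      sprintf("%d episodic, %d control", nrow(ep), nrow(ctl))),
    conditions_balanced = list(
      nrow(ep) == nrow(ctl),
      sprintf("%d vs %d trials", nrow(ep), nrow(ctl))),
    episodic_trials_tagged = list(
      nrow(ep) > 0 && !anyNA(ep$tag) && all(nzchar(ep$tag)),
      sprintf("%d untagged", sum(is.na(ep$tag) | !nzchar(ep$tag)))),
    control_trials_untagged = list(
      all(is.na(ctl$tag)),
      sprintf("%d tagged", sum(!is.na(ctl$tag)))),
    delays_at_least_one_day = list(
      all(trials$delay_days >= 1),
      sprintf("min delay %s", format(min(trials$delay_days)))),
    control_delays_within_episodic_range = list(
      nrow(ep) > 0 && all(ctl$delay_days <= max(ep$delay_days)),
      sprintf("max control %s vs max episodic %s",
              format(suppressWarnings(max(ctl$delay_days))),
              format(suppressWarnings(max(ep$delay_days))))),
    linear_amounts_span_range = list(
      nrow(lin) > 0 &&
        isTRUE(all.equal(range(lin$amount_ll), cfg$linear_range)),
      sprintf("observed [%s, %s], configured [%s, %s]",
              format(min(lin$amount_ll)), format(max(lin$amount_ll)),
              format(cfg$linear_range[1]), format(cfg$linear_range[2]))),
    amounts_exceed_immediate = list(
      all(trials$amount_ll > cfg$ss_amount),
      sprintf("min amount %s vs immediate %s",
              format(min(trials$amount_ll)), format(cfg$ss_amount)))
  )
  tibble::tibble(
    check = names(checks),
    pass = purrr::map_lgl(checks, 1),
    detail = purrr::map_chr(checks, 2)
  )
}

#' Pick the payout trial
#'
#' One trial is randomly selected for real payout at the end of a session.
#'
#' @param trials A trial table.
#' @param seed Optional integer seed.
#' @return A single trial row.
#' @export
pick_payout_trial <- function(trials, seed = NULL) {
  pick <- function() trials[sample.int(nrow(trials), 1), , drop = FALSE]
  if (!is.null(seed)) withr::with_seed(seed, pick()) else pick()
}

#' Plot a designed trial set
#'
#' Amount against delay, coloured by condition and shaped by whether the
#' amount came from the linear grid or the indifference-tailored draw.
#'
#' @param trials A `td_trialset`.
#' @return A ggplot object.
#' @method autoplot td_trialset
#' @export
autoplot.td_trialset <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delay_days, y = .data$amount_ll,
                               colour = .data$condition,
                               shape = .data$amount_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Delay (days)", y = "Larger-later amount (euros)",
                  colour = "Condition", shape = "Amount half") +
    ggplot2::theme_minimal()
}
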