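#' Specification of a synthetic two-group, two-condition cohort
#'
#' Describes the generative model of a simulated study: a pathological
#' gambler group and a matched control group, each participant completing
#' an episodic and a control condition, with individual log discount rates
#' and log decision noise drawn from group-by-condition normal
#' distributions. The default magnitudes are package choices calibrated to
#' plausible day-scale discounting (control-group mean log(k) of -4.5, a
#' +0.7 gambler offset, a -0.2 episodic condition effect so that episodic
#' tags reduce discounting); they are not estimates from any data set.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param trials_per_participant Total trials per participant, split evenly
#'   between the two conditions by the task designer.
#' @param mean_log_k Named vector `c(control = , gambler = )`: group means
#'   of log(k) in the control condition.
#' @param condition_effect Shift of mean log(k) in the episodic condition
#'   (negative = shallower discounting under episodic tags; its negative is
#'   the expected tag-effect).
#' @param sd_log_k Between-participant SD of log(k) within each
#'   group-by-condition cell.
#' @param mean_log_beta,sd_log_beta Mean and SD of log softmax temperature
#'   (euros, log scale), identical across cells.
#' @param rho Correlation between a participant's two condition-specific
#'   parameters (same parameter, control vs. episodic).
#' @param model Generating model (one of the four candidates).
#' @param mean_log_s,sd_log_s Constant-sensitivity exponent distribution
#'   (log scale; used only when `model = "constant_sensitivity"`).
#' @param itch_weights,itch_weight_sd Group-level mean ITCH weights and
#'   their between-participant SD (used only when `model = "itch"`).
#' @param severity_mean,severity_sd Named means (`control`, `gambler`) and
#'   common SD of the placeholder addiction-severity covariate.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @return A list of class `td_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 24, trials_per_participant = 120,
                        mean_log_k = c(control = -4.5, gambler = -3.8),
                        condition_effect = -0.2, sd_log_k = 1,
                        mean_log_beta = 0.7, sd_log_beta = 0.5, rho = 0.7,
                        model = "hyperbolic",
                        mean_log_s = 0, sd_log_s = 0.25,
                        itch_weights = c(b_intercept = -0.5,
                                         b_amount_abs = 0.08,
                                         b_amount_rel = 1.5,
                                         b_delay_abs = -0.015,
                                         b_delay_rel = -0.4),
                        itch_weight_sd = 0.15,
                        severity_mean = c(control = -0.8, gambler = 0.8),
                        severity_sd = 0.6, seed = 1) {
  model <- match.arg(model, TD_MODELS)
  if (n_per_group < 2 || sd_log_k <= 0 || sd_log_beta <= 0 ||
      abs(rho) >= 1 || trials_per_participant %% 2 != 0) {
    abort("Invalid cohort spec: need n_per_group >= 2, positive SDs, |rho| < 1 and an even trial count.",
          class = "discountr_validation_error")
  }
  if (!all(c("control", "gambler") %in% names(mean_log_k))) {
    abort("`mean_log_k` must name both groups.",
          class = "discountr_validation_error")
  }
  structure(list(n_per_group = n_per_group,
                 trials_per_participant = trials_per_participant,
                 mean_log_k = mean_log_k, condition_effect = condition_effect,
                 sd_log_k = sd_log_k, mean_log_beta = mean_log_beta,
                 sd_log_beta = sd_log_beta, rho = rho, model = model,
                 mean_log_s = mean_log_s, sd_log_s = sd_log_s,
                 itch_weights = validate_itch_weights(itch_weights),
                 itch_weight_sd = itch_weight_sd,
                 severity_mean = severity_mean, severity_sd = severity_sd,
                 seed = seed),
            class = "td_cohort_spec")
}

# one correlated pair per participant with given marginal means/sds
draw_pair <- function(n, mean_c, mean_e, sd, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(control = mean_c + sd * z1, episodic = mean_e + sd * z2)
}

#' Simulate binary choices from a model's choice probabilities
#'
#' Draws one Bernoulli choice per trial from the model's probability of
#' choosing the larger-later option given the supplied parameters.
#'
#' @inheritParams choice_prob
#' @param seed Optional integer seed.
#' @return The trial table with a `choice_ll` column.
#' @export
simulate_choices <- function(trials, params, model = "hyperbolic",
                             ss_amount = 20, seed = NULL) {
  draw <- function() {
    p <- choice_prob(trials, params, model = model, ss_amount = ss_amount)$p_ll
    trials$choice_ll <- rbinom(length(p), 1, p)
    trials
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Simulate a complete synthetic cohort with retained ground truth
#'
#' Forward-simulates the full study pipeline: individual
#' participant-by-condition parameters are drawn from the spec's
#' group-by-condition normals; each participant gets a personal list of
#' five to seven future events (delays up to ~200 days) and a two-condition
#' trial set from [build_trials()], using the participant's true
#' control-condition discount rate as the "pretest" rate; choices are then
#' drawn from the generating model's choice probabilities. The ground truth
#' is always returned alongside the data — every synthetic run is a
#' recovery experiment.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `td_cohort` with elements `trials` (a trial
#'   table across all participants) and `truth` (a list: `params` — the
#'   true per-participant, per-condition parameter tibble including the
#'   severity covariate; `spec`; `seed`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "td_cohort_spec"))
  withr::with_seed(spec$seed, {
    groups <- c("control", "gambler")
    params <- purrr::map_dfr(groups, function(g) {
      n <- spec$n_per_group
      ids <- sprintf("%s_%02d", ifelse(g == "gambler", "pg", "hc"), seq_len(n))
      lk <- draw_pair(n, spec$mean_log_k[[g]],
                      spec$mean_log_k[[g]] + spec$condition_effect,
                      spec$sd_log_k, spec$rho)
      lb <- draw_pair(n, spec$mean_log_beta, spec$mean_log_beta,
                      spec$sd_log_beta, spec$rho)
      sev <- rnorm(n, spec$severity_mean[[g]], spec$severity_sd)
      out <- tibble::tibble(
        participant_id = rep(ids, 2),
        group = g,
        condition = rep(c("control", "episodic"), each = n),
        log_k = c(lk$control, lk$episodic),
        log_beta = c(lb$control, lb$episodic),
        severity = rep(sev, 2))
      if (spec$model == "constant_sensitivity") {
        ls <- draw_pair(n, spec$mean_log_s, spec$mean_log_s, spec$sd_log_s,
                        spec$rho)
        out$s <- exp(c(ls$control, ls$episodic))
      }
      if (spec$model == "itch") {
        for (wn in ITCH_WEIGHTS) {
          wp <- draw_pair(n, spec$itch_weights[[wn]], spec$itch_weights[[wn]],
                          spec$itch_weight_sd, spec$rho)
          out[[wn]] <- c(wp$control, wp$episodic)
        }
      }
      out
    })

    trials <- purrr::map_dfr(unique(params$participant_id), function(id) {
      rows <- params[params$participant_id == id, ]
      n_ev <- sample(5:7, 1)
      events <- tibble::tibble(
        label = sprintf("%s_event_%d", id, seq_len(n_ev)),
        delay_days = sort(sample(3:200, n_ev)))
      k_pre <- exp(rows$log_k[rows$condition == "control"])
      design <- build_trials(k_pre, events,
                             design_config(n_trials = spec$trials_per_participant))
      tibble::tibble(participant_id = id, group = rows$group[1],
                     condition = design$condition,
                     amount_ll = design$amount_ll,
                     delay_days = design$delay_days, tag = design$tag)
    })
    trials <- simulate_choices(trials, params, model = spec$model)
    structure(list(trials = trials,
                   truth = list(params = params, spec = spec, seed = spec$seed)),
              class = "td_cohort")
  })
}

#' @export
print.td_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x 2 conditions, %d trials (%s truth, seed %d)\n",
              dplyr::n_distinct(x$trials$participant_id), nrow(x$trials),
              x$truth$spec$model, x$truth$seed))
  invisible(x)
}

#' Write a simulated cohort and its ground truth
#'
#' The trial table goes to `trials.csv`, the truth (true parameters, spec
#' constants, seed) to `truth.json`. Truth is always written: a simulation
#' without its generating parameters cannot be used as a recovery
#' experiment.
#'
#' @param cohort A `td_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "td_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  truth <- cohort$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Small deterministic fixtures shared across tests and examples
#'
#' A bundle of tiny canned datasets: `one_participant` (one participant,
#' both conditions, choices simulated from known parameters),
#' `two_participants` (a minimal cohort that fits end-to-end in seconds),
#' `all_ll` (a degenerate always-delayed responder), and `flat`
#' (information-free coin-flip choices, as produced by an extremely large
#' decision temperature). The same seed always yields the same bundle.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, each fixture is also written
#'   as `<name>.csv`.
#' @return Named list of trial tibbles.
#' @export
fixture_suite <- function(seed = 42, dir = NULL) {
  fixtures <- withr::with_seed(seed, {
    base_events <- tibble::tibble(
      label = paste0("event_", 1:5),
      delay_days = c(5, 21, 60, 120, 180))
    mk <- function(id, group, log_k, log_beta, n_trials = 32) {
      design <- build_trials(exp(log_k), base_events,
                             design_config(n_trials = n_trials))
      tibble::tibble(participant_id = id, group = group,
                     condition = design$condition,
                     amount_ll = design$amount_ll,
                     delay_days = design$delay_days, tag = design$tag)
    }
    p1 <- mk("p1", "control", -4.2, 0.5)
    one <- simulate_choices(
      p1, tibble::tibble(participant_id = "p1",
                         condition = c("control", "episodic"),
                         log_k = -4.2, log_beta = 0.5))
    p2 <- dplyr::bind_rows(
      mk("p1", "control", -4.2, 0.5),
      dplyr::mutate(mk("p2", "gambler", -3.2, 0.5),
                    participant_id = "p2"))
    two <- simulate_choices(
      p2, tibble::tibble(participant_id = rep(c("p1", "p2"), each = 2),
                         condition = rep(c("control", "episodic"), 2),
                         log_k = rep(c(-4.2, -3.2), each = 2),
                         log_beta = 0.5))
    all_ll <- dplyr::mutate(mk("p_ll", "control", -4.5, 0.5), choice_ll = 1L)
    flat <- dplyr::mutate(mk("p_flat", "control", -4.5, 0.5),
                          choice_ll = rbinom(dplyr::n(), 1, 0.5))
    list(one_participant = one, two_participants = two, all_ll = all_ll,
         flat = flat)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    purrr::iwalk(fixtures, function(x, nm) {
      write_trials(x, file.path(dir, paste0(nm, ".csv")))
    })
  }
  fixtures
}
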