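# shared fixtures and shortcuts, all generated in code

five_events <- function() {
  tibble::tibble(label = paste0("event_", 1:5),
                 delay_days = c(5, 21, 60, 120, 180))
}

# a hand-written trial table small enough to reason about
tiny_trials <- function(choices = c(1, 0, 1, 1, 0)) {
  tibble::tibble(
    participant_id = "p1",
    group = "control",
    condition = c("control", "control", "episodic", "episodic", "control"),
    amount_ll = c(40, 25, 65.3, 90, 30),
    delay_days = c(30, 10, 45, 120, 60),
    choice_ll = choices
  )
}

tiny_params <- function(log_k = log(0.02), log_beta = log(2)) {
  tibble::tibble(participant_id = "p1",
                 condition = c("control", "episodic"),
                 log_k = log_k, log_beta = log_beta)
}

# brute-force double-loop WAIC reference, deliberately naive
waic_by_hand <- function(ll) {
  n <- nrow(ll); S <- ncol(ll)
  lppd <- 0; p_waic <- 0
  for (i in seq_len(n)) {
    mean_lik <- 0
    for (s in seq_len(S)) mean_lik <- mean_lik + exp(ll[i, s]) / S
    lppd <- lppd + log(mean_lik)
    if (S > 1) {
      mu <- mean(ll[i, ])
      v <- 0
      for (s in seq_len(S)) v <- v + (ll[i, s] - mu)^2
      p_waic <- p_waic + v / (S - 1)
    }
  }
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

# reduced sampler settings for fast fits in unit tests; gates relaxed so
# short chains do not warn about the production-quality thresholds
quick_config <- function(seed = 11, chains = 2, draws = 300, warmup = 300) {
  hier_config(chains = chains, draws = draws, warmup = warmup, seed = seed,
              rhat_max = Inf, ess_min = 0)
}

small_cohort <- function(seed = 3, n_per_group = 3, trials = 24, ...) {
  simulate_cohort(cohort_spec(n_per_group = n_per_group,
                              trials_per_participant = trials,
                              seed = seed, ...))
}
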