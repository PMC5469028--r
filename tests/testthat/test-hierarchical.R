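test_that("the sampler configuration enforces its invariants", {
  expect_error(hier_config(chains = 1), class = "discountr_validation_error")
  expect_error(hier_config(priors = list(sigma_log_k = -1)),
               class = "discountr_validation_error")
})

test_that("two fits with the same seed and config are identical", {
  co <- small_cohort(seed = 3)
  f1 <- fit_hierarchical(co$trials, config = quick_config(seed = 11,
                                                          draws = 150,
                                                          warmup = 150))
  f2 <- fit_hierarchical(co$trials, config = quick_config(seed = 11,
                                                          draws = 150,
                                                          warmup = 150))
  expect_identical(f1$draws, f2$draws)
  expect_identical(point_estimates(f1), point_estimates(f2))
  expect_identical(f1$config_hash, f2$config_hash)
})

test_that("an always-delayed responder pulls log(k) below its prior mean", {
  fx <- fixture_suite(seed = 42)
  one <- fx$all_ll
  fit <- fit_hierarchical(one, config = quick_config(seed = 5))
  est <- point_estimates(fit)
  expect_true(all(est$log_k < -4.5))
})

test_that("a participant with an empty condition is a validation error", {
  co <- small_cohort(seed = 8)
  broken <- co$trials[!(co$trials$participant_id == co$trials$participant_id[1] &
                          co$trials$condition == "episodic"), ]
  expect_error(fit_hierarchical(broken, config = quick_config()),
               class = "discountr_validation_error")
})

test_that("point estimates are the column means / medians of the stored draws", {
  co <- small_cohort(seed = 3, n_per_group = 2, trials = 16)
  fit <- fit_hierarchical(co$trials, config = quick_config(draws = 100,
                                                           warmup = 150))
  est <- point_estimates(fit, "posterior_mean")
  cols <- paste0("logk[", fit$units$unit, "]")
  expect_equal(est$log_k, unname(colMeans(fit$draws[, cols])))
  med <- point_estimates(fit, "posterior_median")
  expect_equal(med$log_k, unname(apply(fit$draws[, cols], 2, median)))
  # median of an even draw count is the midpoint of the central pair
  expect_equal(median(c(1, 3)), 2)
  # asking for a parameter the model does not have is a lookup error
  hacked <- fit
  hacked$model <- "constant_sensitivity"
  expect_error(point_estimates(hacked), class = "discountr_lookup_error")
})

test_that("the stored pointwise log-likelihood matrix is recomputable from draws", {
  co <- small_cohort(seed = 3, n_per_group = 2, trials = 16)
  for (model in c("hyperbolic", "itch")) {
    fit <- fit_hierarchical(co$trials, model = model,
                            config = quick_config(draws = 80, warmup = 120))
    expect_equal(fit$loglik, loglik_matrix(fit), tolerance = 1e-12)
    expect_equal(dim(fit$loglik), c(nrow(co$trials), nrow(fit$draws)))
    expect_true(all(is.finite(fit$loglik)))
    # spot-check one draw against the single-draw likelihood path
    s <- 17
    est <- if (model == "itch") {
      p <- point_estimates(fit)
      for (m in seq_along(discountr:::ITCH_WEIGHTS)) {
        p[[discountr:::ITCH_WEIGHTS[m]]] <-
          unname(fit$draws[s, paste0("w[", fit$units$unit, ",", m, "]")])
      }
      p
    } else {
      tibble::tibble(
        participant_id = fit$units$participant_id,
        condition = fit$units$condition,
        log_k = unname(fit$draws[s, paste0("logk[", fit$units$unit, "]")]),
        log_beta = unname(fit$draws[s, paste0("logb[", fit$units$unit, "]")]))
    }
    expect_equal(fit$loglik[, s],
                 pointwise_loglik(fit$trials, est, model = model),
                 tolerance = 1e-10)
  }
})

test_that("hierarchical pooling shrinks individual estimates relative to per-cell ML", {
  co <- simulate_cohort(cohort_spec(n_per_group = 4,
                                    trials_per_participant = 40, seed = 19))
  fit <- fit_hierarchical(co$trials, config = quick_config(seed = 2))
  hier <- point_estimates(fit)
  mle <- fit_mle(co$trials)
  j <- dplyr::inner_join(hier, mle, by = c("participant_id", "condition"),
                         suffix = c("_hier", "_mle"))
  expect_lt(var(j$log_k_hier), var(j$log_k_mle))
})

test_that("with information-free choices the posterior approximates the prior", {
  fx <- fixture_suite(seed = 42)
  flat <- fx$flat
  # four pseudo-participants of coin-flip choices to give the hierarchy
  # something to pool over
  flat4 <- purrr::map_dfr(1:4, function(i) {
    dplyr::mutate(flat, participant_id = paste0("p", i),
                  choice_ll = withr::with_seed(100 + i,
                                               rbinom(dplyr::n(), 1, 0.5)))
  })
  fit <- fit_hierarchical(flat4, config = quick_config(seed = 23, draws = 800,
                                                       warmup = 600))
  cols <- paste0("logk[", fit$units$unit, "]")
  post_sd <- sd(as.numeric(fit$draws[, cols]))
  # marginal prior SD of an individual log(k), by direct Monte Carlo from
  # the hyperprior (mu ~ N(-4.5, 2), sigma ~ half-N(2))
  prior_sd <- withr::with_seed(99, {
    mu <- rnorm(2e5, -4.5, 2)
    sig <- abs(rnorm(2e5, 0, 2))
    sd(rnorm(2e5, mu, sig))
  })
  expect_lt(abs(post_sd - prior_sd) / prior_sd, 0.25)
})

test_that("convergence gates flag short runs instead of failing silently", {
  co <- small_cohort(seed = 3, n_per_group = 2, trials = 16)
  cfg <- hier_config(chains = 2, draws = 40, warmup = 40, seed = 1,
                     rhat_max = 1.0001, ess_min = 1e6)
  expect_warning(fit <- fit_hierarchical(co$trials, config = cfg),
                 "Convergence gates")
  expect_false(fit$converged)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  expect_equal(nrow(fit$diagnostics), ncol(fit$draws))
})

test_that("fit outputs write as delimited text with metadata", {
  co <- small_cohort(seed = 3, n_per_group = 2, trials = 16)
  fit <- fit_hierarchical(co$trials, config = quick_config(draws = 60,
                                                           warmup = 100))
  d <- withr::local_tempdir()
  write_fit(fit, d)
  expect_true(all(file.exists(file.path(d, c("summary.csv", "estimates.csv",
                                             "draws.csv", "loglik.csv",
                                             "metadata.json")))))
  meta <- jsonlite::fromJSON(file.path(d, "metadata.json"))
  expect_equal(meta$model, "hyperbolic")
  expect_equal(meta$seed, fit$seed)
})

test_that("a one-point group difference in log(k) is recovered in direction across replicates", {
  # gambler mean log(k) one unit above controls, as in the recovery design
  separated <- vapply(1:20, function(r) {
    co <- simulate_cohort(cohort_spec(
      n_per_group = 12, trials_per_participant = 60,
      mean_log_k = c(control = -4.5, gambler = -3.5), seed = 5000 + r))
    fit <- fit_hierarchical(co$trials,
                            config = quick_config(seed = r, draws = 200,
                                                  warmup = 250))
    est <- point_estimates(fit)
    mean(est$log_k[est$group == "gambler"]) >
      mean(est$log_k[est$group == "control"])
  }, logical(1))
  expect_gte(mean(separated), 0.95)
})
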