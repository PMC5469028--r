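#' Configuration for the hierarchical MCMC fit
#'
#' Sampler and prior settings for [fit_hierarchical()]. Individual
#' participant-by-condition parameters are drawn from group-by-condition
#' normal distributions on the log scale; the group-level means and
#' standard deviations get weakly informative normal and half-normal
#' hyperpriors chosen to span empirically plausible day-scale discount
#' rates without dominating a session of a hundred or more trials.
#'
#' @param chains Number of MCMC chains (>= 2).
#' @param draws Kept draws per chain after warmup.
#' @param warmup Warmup iterations per chain (split between JAGS adaptation
#'   and burn-in).
#' @param seed Integer seed; fixes adaptation, burn-in and sampling so a
#'   fit is reproducible run-to-run on the same platform.
#' @param priors Named list of hyperprior constants; see defaults in the
#'   function signature. `mu_*` entries are `c(mean, sd)` of the normal
#'   hyperprior on the group-level mean; `sigma_*` entries are the scale of
#'   the half-normal hyperprior on the group-level SD.
#' @param rhat_max,ess_min Convergence gates: largest admissible split
#'   R-hat and smallest admissible effective sample size over all sampled
#'   parameters. A fit outside the gates is returned flagged
#'   (`converged = FALSE`) with a warning, never silently.
#' @return A list of class `td_hier_config`.
#' @export
hier_config <- function(chains = 4, draws = 1000, warmup = 1000, seed = 1,
                        priors = list(
                          mu_log_k = c(-4.5, 2), sigma_log_k = 2,
                          mu_log_beta = c(1, 2), sigma_log_beta = 2,
                          mu_log_s = c(0, 1), sigma_log_s = 1,
                          mu_itch = c(0, 5), sigma_itch = 2),
                        rhat_max = 1.01, ess_min = 400) {
  if (chains < 2 || draws < 1 || warmup < 2) {
    abort("Need chains >= 2, draws >= 1, warmup >= 2.",
          class = "discountr_validation_error")
  }
  defaults <- list(mu_log_k = c(-4.5, 2), sigma_log_k = 2,
                   mu_log_beta = c(1, 2), sigma_log_beta = 2,
                   mu_log_s = c(0, 1), sigma_log_s = 1,
                   mu_itch = c(0, 5), sigma_itch = 2)
  priors <- utils::modifyList(defaults, priors)
  if (any(purrr::map_dbl(priors[c("sigma_log_k", "sigma_log_beta",
                                  "sigma_log_s", "sigma_itch")], 1) <= 0) ||
      priors$mu_log_k[2] <= 0 || priors$mu_log_beta[2] <= 0) {
    abort("Prior scales must be > 0.", class = "discountr_validation_error")
  }
  structure(list(chains = chains, draws = draws, warmup = warmup,
                 seed = seed, priors = priors,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "td_hier_config")
}

# JAGS code: hyperpriors per group x condition cell, individual parameters
# per participant x condition unit, Bernoulli likelihood per trial
jags_code <- function(model) {
  hyper_kb <- "
  for (g in 1:G) {
    mu_k[g] ~ dnorm(pr_mu_k[1], pow(pr_mu_k[2], -2))
    sig_k[g] ~ dnorm(0, pow(pr_sig_k, -2)) T(0,)
    mu_b[g] ~ dnorm(pr_mu_b[1], pow(pr_mu_b[2], -2))
    sig_b[g] ~ dnorm(0, pow(pr_sig_b, -2)) T(0,)
  }"
  unit_kb <- "
  for (j in 1:J) {
    logk[j] ~ dnorm(mu_k[cell[j]], pow(sig_k[cell[j]], -2))
    logb[j] ~ dnorm(mu_b[cell[j]], pow(sig_b[cell[j]], -2))
  }"
  # the same probability floor as the R likelihood: keeps dbern consistent
  # when ilogit saturates to 0/1 in double precision
  lik <- function(sv) sprintf("
  for (i in 1:N) {
    sv[i] <- %s
    p[i] <- max(min(ilogit((sv[i] - ss) / exp(logb[id[i]])), 1 - 1e-9), 1e-9)
    y[i] ~ dbern(p[i])
  }", sv)
  switch(model,
    hyperbolic = paste0("model {", hyper_kb, unit_kb,
      lik("amt[i] / (1 + exp(logk[id[i]]) * delay[i])"), "\n}"),
    exponential = paste0("model {", hyper_kb, unit_kb,
      lik("amt[i] * exp(-exp(logk[id[i]]) * delay[i])"), "\n}"),
    constant_sensitivity = paste0("model {", hyper_kb, "
  for (g in 1:G) {
    mu_s[g] ~ dnorm(pr_mu_s[1], pow(pr_mu_s[2], -2))
    sig_s[g] ~ dnorm(0, pow(pr_sig_s, -2)) T(0,)
  }", unit_kb, "
  for (j in 1:J) {
    logs[j] ~ dnorm(mu_s[cell[j]], pow(sig_s[cell[j]], -2))
  }",
      lik("amt[i] * exp(-pow(exp(logk[id[i]]) * delay[i], exp(logs[id[i]])))"),
      "\n}"),
    itch = "model {
  for (g in 1:G) {
    for (m in 1:5) {
      mu_w[g, m] ~ dnorm(pr_mu_w[1], pow(pr_mu_w[2], -2))
      sig_w[g, m] ~ dnorm(0, pow(pr_sig_w, -2)) T(0,)
    }
  }
  for (j in 1:J) {
    for (m in 1:5) {
      w[j, m] ~ dnorm(mu_w[cell[j], m], pow(sig_w[cell[j], m], -2))
    }
  }
  for (i in 1:N) {
    eta[i] <- w[id[i], 1] + w[id[i], 2] * dx[i] + w[id[i], 3] * dxr[i] +
              w[id[i], 4] * dt[i] + w[id[i], 5] * dtr[i]
    p[i] <- max(min(ilogit(eta[i]), 1 - 1e-9), 1e-9)
    y[i] ~ dbern(p[i])
  }
}")
}

# split-R-hat over a draws array (iterations x chains) for one parameter
split_rhat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit the hierarchical Bayesian discounting model
#'
#' Estimates per-participant, per-condition parameters of one of the four
#' candidate intertemporal-choice models by MCMC, with individual
#' parameters pooled toward group-by-condition normal distributions on the
#' log scale (pathological gamblers and controls get separate hyperpriors,
#' as do the episodic and control conditions). The value-based models pair
#' the model's subjective value with the softmax rule; the intertemporal
#' choice heuristic uses its own logistic rule. Sampling runs in JAGS; the
#' probability model, priors, diagnostics and the trials-by-samples
#' pointwise log-likelihood matrix (recomputed in R from the stored draws)
#' are the package's own.
#'
#' @param trials A trial table (see [read_trials()]); every participant
#'   must have trials in every condition present in the data.
#' @param model One of `"hyperbolic"`, `"exponential"`,
#'   `"constant_sensitivity"`, `"itch"`.
#' @param config A [hier_config()].
#' @param ss_amount Fixed immediate amount, euros.
#' @return A `td_fit` object: stored draws (`draws`, a samples-by-parameter
#'   matrix, plus the underlying `coda` chains), the unit table mapping
#'   parameters to participants, the pointwise log-likelihood matrix
#'   (`loglik`, trials by samples), per-parameter convergence diagnostics,
#'   and run metadata (seed, config, config hash). Methods: [tidy()],
#'   [glance()], [point_estimates()], [compute_waic()], [autoplot()].
#' @export
fit_hierarchical <- function(trials, model = "hyperbolic",
                             config = hier_config(), ss_amount = 20) {
  model <- match.arg(model, TD_MODELS)
  stopifnot(inherits(config, "td_hier_config"))
  trials <- validate_trials(trials, ss_amount = ss_amount,
                            allow_dominated = TRUE)

  conditions <- sort(unique(trials$condition))
  by_part <- dplyr::summarise(dplyr::group_by(trials, .data$participant_id),
                              n_cond = dplyr::n_distinct(.data$condition))
  if (any(by_part$n_cond < length(conditions))) {
    bad <- by_part$participant_id[by_part$n_cond < length(conditions)]
    abort(paste0("Participant(s) with an empty condition: ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "discountr_validation_error")
  }

  units <- dplyr::distinct(trials, .data$participant_id, .data$group,
                           .data$condition)
  units <- dplyr::arrange(units, .data$participant_id, .data$condition)
  units$unit <- seq_len(nrow(units))
  cells <- dplyr::distinct(units, .data$group, .data$condition)
  cells <- dplyr::arrange(cells, .data$group, .data$condition)
  cells$cell <- seq_len(nrow(cells))
  units <- dplyr::left_join(units, cells, by = c("group", "condition"))
  trials_ix <- dplyr::left_join(
    trials, dplyr::select(units, "participant_id", "condition", "unit"),
    by = c("participant_id", "condition"))

  pr <- config$priors
  data <- list(N = nrow(trials), J = nrow(units), G = nrow(cells),
               y = trials$choice_ll, id = trials_ix$unit, cell = units$cell)
  if (model == "itch") {
    dx <- trials$amount_ll - ss_amount
    dt <- trials$delay_days - 0
    data$dx <- dx
    data$dxr <- dx / ((trials$amount_ll + ss_amount) / 2)
    data$dt <- dt
    data$dtr <- ifelse(dt == 0, 0, dt / (trials$delay_days / 2))
    data$pr_mu_w <- pr$mu_itch
    data$pr_sig_w <- pr$sigma_itch
  } else {
    data$amt <- trials$amount_ll
    data$delay <- trials$delay_days
    data$ss <- ss_amount
    data$pr_mu_k <- pr$mu_log_k
    data$pr_sig_k <- pr$sigma_log_k
    data$pr_mu_b <- pr$mu_log_beta
    data$pr_sig_b <- pr$sigma_log_beta
    if (model == "constant_sensitivity") {
      data$pr_mu_s <- pr$mu_log_s
      data$pr_sig_s <- pr$sigma_log_s
    }
  }

  inits <- purrr::map(seq_len(config$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = config$seed * 100 + ch)
    if (model == "itch") {
      ini$w <- matrix(0, nrow(units), 5)
    } else {
      ini$logk <- rep(pr$mu_log_k[1], nrow(units))
      ini$logb <- rep(pr$mu_log_beta[1], nrow(units))
      if (model == "constant_sensitivity") ini$logs <- rep(0, nrow(units))
    }
    ini
  })

  monitors <- if (model == "itch") c("w", "mu_w", "sig_w")
              else c("logk", "logb", "mu_k", "sig_k", "mu_b", "sig_b")
  if (model == "constant_sensitivity") {
    monitors <- c(monitors, "logs", "mu_s", "sig_s")
  }

  n_adapt <- max(100, config$warmup %/% 2)
  n_burn <- max(1, config$warmup - n_adapt)
  jm <- rjags::jags.model(textConnection(jags_code(model)), data = data,
                          inits = inits, n.chains = config$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  mcmc <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                              progress.bar = "none")

  draws <- do.call(rbind, purrr::map(mcmc, as.matrix))
  pnames <- colnames(draws)
  rhat <- purrr::map_dbl(pnames, function(p) {
    split_rhat(sapply(mcmc, function(ch) as.matrix(ch)[, p]))
  })
  ess <- coda::effectiveSize(mcmc)[pnames]
  diagnostics <- tibble::tibble(term = pnames, rhat = rhat, ess = ess)
  converged <- all(diagnostics$rhat <= config$rhat_max, na.rm = TRUE) &&
    all(diagnostics$ess >= config$ess_min, na.rm = TRUE)
  if (!converged) {
    warn(sprintf(
      "Convergence gates not met (max split R-hat %.3f > %.3f or min ESS %.0f < %.0f); inspect $diagnostics.",
      max(diagnostics$rhat, na.rm = TRUE), config$rhat_max,
      min(diagnostics$ess, na.rm = TRUE), config$ess_min))
  }

  fit <- structure(
    list(model = model, draws = draws, mcmc = mcmc, units = units,
         cells = cells, trials = trials, ss_amount = ss_amount,
         diagnostics = diagnostics, converged = converged, config = config,
         seed = config$seed, config_hash = rlang::hash(config)),
    class = "td_fit")
  fit$loglik <- loglik_matrix(fit)
  fit
}

#' Recompute the trials-by-samples pointwise log-likelihood matrix from
#' stored draws
#'
#' Evaluates, for every posterior draw, the Bernoulli log-likelihood of
#' each observed trial under the fitted model's choice probability (with
#' the same probability clamp as [pointwise_loglik()]). `fit$loglik` stores
#' this matrix at fit time; calling the function again must reproduce it.
#'
#' @param fit A `td_fit`.
#' @return A numeric matrix, trials in rows, kept posterior samples in
#'   columns.
#' @export
loglik_matrix <- function(fit) {
  stopifnot(inherits(fit, "td_fit"))
  trials <- fit$trials
  units <- dplyr::left_join(
    dplyr::select(trials, "participant_id", "condition"),
    dplyr::select(fit$units, "participant_id", "condition", "unit"),
    by = c("participant_id", "condition"))
  ix <- units$unit
  draws <- fit$draws
  S <- nrow(draws)
  N <- nrow(trials)
  unit_mat <- function(stem) {
    cols <- paste0(stem, "[", fit$units$unit, "]")
    t(draws[, cols, drop = FALSE])[ix, , drop = FALSE] # N x S
  }
  if (fit$model == "itch") {
    wmat <- function(m) {
      cols <- paste0("w[", fit$units$unit, ",", m, "]")
      t(draws[, cols, drop = FALSE])[ix, , drop = FALSE]
    }
    dx <- trials$amount_ll - fit$ss_amount
    dxr <- dx / ((trials$amount_ll + fit$ss_amount) / 2)
    dt <- trials$delay_days
    dtr <- ifelse(dt == 0, 0, 2)
    lp <- wmat(1) + wmat(2) * dx + wmat(3) * dxr + wmat(4) * dt + wmat(5) * dtr
    p <- plogis(lp)
  } else {
    K <- exp(unit_mat("logk"))
    B <- exp(unit_mat("logb"))
    sv <- switch(fit$model,
      hyperbolic = trials$amount_ll / (1 + K * trials$delay_days),
      exponential = trials$amount_ll * exp(-K * trials$delay_days),
      constant_sensitivity = {
        S_mat <- exp(unit_mat("logs"))
        trials$amount_ll * exp(-(K * trials$delay_days)^S_mat)
      })
    p <- plogis((sv - fit$ss_amount) / B)
  }
  p <- clamp_prob(p)
  y <- trials$choice_ll
  ll <- matrix(NA_real_, N, S)
  ll[y == 1, ] <- log(p[y == 1, , drop = FALSE])
  ll[y == 0, ] <- log1p(-p[y == 0, , drop = FALSE])
  ll
}
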