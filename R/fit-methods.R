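#' Per-participant, per-condition point estimates from a hierarchical fit
#'
#' Reduces the posterior draws to one value per parameter per participant
#' and condition — the table the group-level behavioural analyses consume.
#' The posterior median of an even number of draws is the midpoint of the
#' two central order statistics (the `stats::median()` convention).
#'
#' @param fit A `td_fit` from [fit_hierarchical()].
#' @param estimator `"posterior_mean"` or `"posterior_median"`.
#' @return A tibble with one row per participant x condition:
#'   `participant_id`, `group`, `condition`, then `log_k` and `log_beta`
#'   (plus `s` for the constant-sensitivity model) or the five ITCH weight
#'   columns.
#' @export
point_estimates <- function(fit,
                            estimator = c("posterior_mean", "posterior_median")) {
  stopifnot(inherits(fit, "td_fit"))
  estimator <- match.arg(estimator)
  est <- if (estimator == "posterior_mean") colMeans(fit$draws)
         else apply(fit$draws, 2, median)
  grab <- function(stem) {
    cols <- paste0(stem, "[", fit$units$unit, "]")
    if (!all(cols %in% names(est))) {
      abort(paste0("Parameter `", stem, "` is not part of the ", fit$model,
                   " model's draws."),
            class = "discountr_lookup_error")
    }
    unname(est[cols])
  }
  out <- dplyr::select(fit$units, "participant_id", "group", "condition")
  if (fit$model == "itch") {
    for (m in seq_along(ITCH_WEIGHTS)) {
      cols <- paste0("w[", fit$units$unit, ",", m, "]")
      out[[ITCH_WEIGHTS[m]]] <- unname(est[cols])
    }
  } else {
    out$log_k <- grab("logk")
    out$log_beta <- grab("logb")
    if (fit$model == "constant_sensitivity") {
      cols <- paste0("logs[", fit$units$unit, "]")
      if (!all(cols %in% colnames(fit$draws))) {
        abort("Parameter `logs` is not part of this fit's draws.",
              class = "discountr_lookup_error")
      }
      s_est <- if (estimator == "posterior_mean") {
        colMeans(exp(fit$draws[, cols, drop = FALSE]))
      } else {
        apply(exp(fit$draws[, cols, drop = FALSE]), 2, median)
      }
      out$s <- unname(s_est)
    }
  }
  out
}

#' @export
print.td_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s fit: %d trials, %d participants, %d draws (%d chains)%s\n",
              x$model, nrow(x$trials),
              dplyr::n_distinct(x$units$participant_id), nrow(x$draws),
              x$config$chains,
              if (x$converged) "" else " [convergence gates NOT met]"))
  invisible(x)
}

#' Tidy posterior summaries of a hierarchical fit
#'
#' @param x A `td_fit`.
#' @param pars `"hyper"` for the group-by-condition hyperparameters (the
#'   default), `"individual"` for the per-participant parameters, or
#'   `"all"`.
#' @param conf_level Width of the posterior quantile interval.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy td_fit
#' @export
tidy.td_fit <- function(x, pars = c("hyper", "individual", "all"),
                        conf_level = 0.95, ...) {
  pars <- match.arg(pars)
  individual <- grepl("^(logk|logb|logs|w)\\[", colnames(x$draws))
  keep <- switch(pars, hyper = !individual, individual = individual,
                 all = rep(TRUE, ncol(x$draws)))
  d <- x$draws[, keep, drop = FALSE]
  a <- (1 - conf_level) / 2
  out <- tibble::tibble(
    term = colnames(d),
    estimate = colMeans(d),
    std.error = apply(d, 2, sd),
    conf.low = apply(d, 2, quantile, probs = a),
    conf.high = apply(d, 2, quantile, probs = 1 - a)
  )
  dplyr::left_join(out, x$diagnostics, by = "term")
}

#' @method glance td_fit
#' @export
glance.td_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_trials = nrow(x$trials),
    n_participants = dplyr::n_distinct(x$units$participant_id),
    n_samples = nrow(x$draws),
    n_chains = x$config$chains,
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    seed = x$seed
  )
}

#' Posterior distributions of the group-level means
#'
#' Density of the group-by-condition hyperparameter means (log discount
#' rate, and log decision noise for the value-based models), faceted by
#' parameter.
#'
#' @param object A `td_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot td_fit
#' @export
autoplot.td_fit <- function(object, ...) {
  stems <- if (object$model == "itch") "mu_w" else c("mu_k", "mu_b")
  keep <- grepl(paste0("^(", paste(stems, collapse = "|"), ")\\["),
                colnames(object$draws))
  d <- object$draws[, keep, drop = FALSE]
  long <- tidyr::pivot_longer(tibble::as_tibble(d), dplyr::everything(),
                              names_to = "term", values_to = "value")
  cell_label <- paste(object$cells$group, object$cells$condition, sep = " / ")
  long$cell <- cell_label[as.integer(sub("^[a-z_]+\\[(\\d+).*", "\\1", long$term))]
  long$parameter <- sub("\\[.*", "", long$term)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$cell)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Group-level posterior draw", y = "Density",
                  colour = "Group / condition") +
    ggplot2::theme_minimal()
}

#' Write posterior outputs as delimited text
#'
#' Writes the posterior summary table, the per-participant point
#' estimates, the full draws matrix and the pointwise log-likelihood
#' matrix as CSV files, plus a JSON metadata sidecar (model, seed, config
#' hash, convergence flag), into a directory.
#'
#' @param fit A `td_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "td_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(fit, pars = "all"), file.path(dir, "summary.csv"),
                   progress = FALSE)
  readr::write_csv(point_estimates(fit), file.path(dir, "estimates.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(fit$draws), file.path(dir, "draws.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(fit$loglik, .name_repair = "unique_quiet"),
                   file.path(dir, "loglik.csv"), progress = FALSE)
  meta <- list(model = fit$model, seed = fit$seed,
               config_hash = fit$config_hash, converged = fit$converged,
               n_trials = nrow(fit$trials), n_samples = nrow(fit$draws))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
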