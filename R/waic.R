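#' Widely applicable information criterion (WAIC) from a pointwise
#' log-likelihood matrix
#'
#' Computes, over a trials-by-samples matrix of pointwise log-likelihoods
#' recorded during MCMC:
#' \itemize{
#'   \item `lppd` — log pointwise predictive density,
#'     \eqn{\sum_i \log(\frac{1}{S}\sum_s \exp(\ell_{is}))}, evaluated with a
#'     log-sum-exp guard so strongly negative log-likelihoods do not
#'     underflow;
#'   \item `p_waic` — the variance-form effective number of parameters,
#'     \eqn{\sum_i \mathrm{Var}_s(\ell_{is})} with the usual `n - 1` sample
#'     variance (0 when a single sample is supplied);
#'   \item `waic` — on the deviance scale, \eqn{-2(\mathrm{lppd} - p_{waic})};
#'     lower is better.
#' }
#'
#' @param loglik Numeric matrix, trials in rows, posterior samples in
#'   columns; all entries finite. A [fit_hierarchical()] result may be passed
#'   directly.
#' @return An object of class `td_waic`: a list with `lppd`, `p_waic`,
#'   `waic`, `n_trials`, `n_samples`. Has [tidy()] and [glance()] methods.
#' @examples
#' ll <- matrix(log(0.5), nrow = 4, ncol = 10)
#' compute_waic(ll)$waic  # -2 * 4 * log(0.5), p_waic = 0
#' @export
compute_waic <- function(loglik) {
  if (inherits(loglik, "td_waic")) return(loglik)
  if (inherits(loglik, "td_fit")) loglik <- loglik$loglik
  if (!is.matrix(loglik) || !is.numeric(loglik) ||
      nrow(loglik) < 1 || ncol(loglik) < 1) {
    abort("`loglik` must be a numeric matrix with >= 1 trial and >= 1 sample.",
          class = "discountr_validation_error")
  }
  if (any(!is.finite(loglik))) {
    abort("`loglik` contains non-finite entries.",
          class = "discountr_validation_error")
  }
  S <- ncol(loglik)
  # log mean exp per row, guarded against underflow
  m <- apply(loglik, 1, max)
  lppd_i <- m + log(rowMeans(exp(sweep(loglik, 1, m))))
  p_i <- if (S > 1) apply(loglik, 1, var) else rep(0, nrow(loglik))
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  structure(
    list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic),
         n_trials = nrow(loglik), n_samples = S),
    class = "td_waic"
  )
}

#' @export
print.td_waic <- function(x, ...) {
  cat(sprintf("WAIC: %.2f (lppd %.2f, p_waic %.2f; %d trials x %d samples)\n",
              x$waic, x$lppd, x$p_waic, x$n_trials, x$n_samples))
  invisible(x)
}

#' @method tidy td_waic
#' @export
tidy.td_waic <- function(x, ...) {
  tibble::tibble(lppd = x$lppd, p_waic = x$p_waic, waic = x$waic)
}

#' @method glance td_waic
#' @export
glance.td_waic <- function(x, ...) {
  tibble::tibble(waic = x$waic, n_trials = x$n_trials, n_samples = x$n_samples)
}

#' Rank candidate models by WAIC
#'
#' Orders a set of fitted models by WAIC (ascending; lower is better) and
#' reports each model's difference from the best.
#'
#' @param results A named list of `td_waic` objects (names are model labels),
#'   or a list of [fit_hierarchical()] fits, which are reduced with
#'   [compute_waic()] first.
#' @return A tibble with columns `model`, `waic`, `lppd`, `p_waic`,
#'   `delta_waic`, ordered best first (`delta_waic` of the best model is 0).
#' @examples
#' a <- compute_waic(matrix(log(0.6), 2, 4))
#' b <- compute_waic(matrix(log(0.4), 2, 4))
#' rank_models(list(first = a, second = b))
#' @export
rank_models <- function(results) {
  if (length(results) < 2) {
    abort("Need >= 2 model results to rank.",
          class = "discountr_validation_error")
  }
  nm <- names(results)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort("`results` must be a named list.",
          class = "discountr_validation_error")
  }
  if (anyDuplicated(nm)) {
    abort("Duplicate model names in `results`.",
          class = "discountr_validation_error")
  }
  results <- purrr::map(results, compute_waic)
  out <- purrr::map2_dfr(results, nm, function(w, n) {
    tibble::tibble(model = n, waic = w$waic, lppd = w$lppd, p_waic = w$p_waic)
  })
  out <- dplyr::arrange(out, .data$waic)
  out$delta_waic <- out$waic - out$waic[1]
  out
}

#' Plot a WAIC model ranking
#'
#' Dot plot of the WAIC difference from the best-fitting model.
#'
#' @param ranking A tibble from [rank_models()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$delta_waic,
                               y = stats::reorder(.data$model, -.data$delta_waic))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = expression(Delta * "WAIC vs. best model"), y = NULL) +
    ggplot2::theme_minimal()
}
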