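#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted parameter-recovery result
#'
#' @param x a `tc_fit` object from [run_pso()] or [fit_key_parameters()].
#' @param ... unused.
#' @return A tibble with one row per fitted dimension: `term`, `estimate`
#'   and, when the truth was supplied, `truth` and `error`.
#' @export
tidy.tc_fit <- function(x, ...) {
  terms <- names(x$best_x)
  if (is.null(terms)) terms <- paste0("x", seq_along(x$best_x))
  out <- tibble::tibble(term = terms, estimate = unname(x$best_x))
  if (!is.null(x$truth)) {
    out$truth <- x$truth
    out$error <- out$estimate - out$truth
  }
  out
}

#' Glance at a fitted parameter-recovery result
#'
#' @inheritParams tidy.tc_fit
#' @return A one-row tibble: `scheme`, `best_q`, `iterations`, `termination`,
#'   `n_nonfinite` and (when the truth was supplied) `err`/`ln_err`.
#' @export
glance.tc_fit <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, best_q = x$best_q,
                 iterations = x$iterations_used, termination = x$termination,
                 n_nonfinite = x$n_nonfinite,
                 err = if (is.null(x$e_t)) NA_real_ else x$e_t,
                 ln_err = if (is.null(x$ln_e_t)) NA_real_ else x$ln_e_t)
}

#' Plot a simulated voltage trace with its stimulus
#'
#' @param object a `tc_sim` tibble from [simulate_tc()].
#' @param ... unused.
#' @return A ggplot: membrane potential over time, with the applied current
#'   drawn underneath (rescaled) and pulse onsets marked.
#' @export
autoplot.tc_sim <- function(object, ...) {
  onsets <- attr(object, "pulse_onsets")
  base <- min(object$v) - 15
  cur <- base + 2 * object$i_sm
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = cur), colour = "steelblue",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$v), linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  title = "TC model voltage trace",
                  subtitle = "applied pulse current shown below the trace") +
    ggplot2::theme_minimal()
}

#' Plot the convergence of a fit
#'
#' @param object a `tc_fit` object.
#' @param ... unused.
#' @return A ggplot of the global-best fitness against the iteration
#'   counter (log fitness scale).
#' @export
autoplot.tc_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$k, y = .data$gbest_q)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration k", y = "global best fitness q",
                  title = paste("PSO convergence,", object$scheme, "scheme")) +
    ggplot2::theme_minimal()
}

#' Plot the per-iteration trajectories of the fitted parameters
#'
#' @param fit a `tc_fit` from [fit_key_parameters()] (3-dimensional search).
#' @param truth optional true triple to draw as horizontal references
#'   (taken from the fit when present).
#' @return A faceted ggplot of the global-best value of each key parameter
#'   against the iteration counter.
#' @export
plot_trajectories <- function(fit, truth = fit$truth) {
  stopifnot(inherits(fit, "tc_fit"))
  d <- length(fit$best_x)
  terms <- names(fit$best_x)
  if (is.null(terms)) terms <- paste0("x", seq_len(d))
  long <- fit$history |>
    dplyr::select("k", dplyr::all_of(paste0("x", seq_len(d)))) |>
    stats::setNames(c("k", terms)) |>
    tidyr::pivot_longer(-"k", names_to = "term", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration k", y = "global-best parameter value") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    ref <- tibble::tibble(term = terms, value = truth)
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = 2, colour = "red3")
  }
  p
}

#' Plot a scheme comparison
#'
#' @param object a `tc_comparison` tibble from [run_comparison()].
#' @param ... unused.
#' @return A ggplot of the log parameter error per inertia scheme (points
#'   per seed plus median crossbar).
#' @export
autoplot.tc_comparison <- function(object, ...) {
  med <- comparison_summary(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scheme, y = .data$ln_err)) +
    ggplot2::geom_point(alpha = 0.7, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1)) +
    ggplot2::geom_crossbar(data = med,
                           ggplot2::aes(y = .data$median_ln_err,
                                        ymin = .data$median_ln_err,
                                        ymax = .data$median_ln_err),
                           width = 0.4, colour = "red3") +
    ggplot2::labs(x = "inertia scheme", y = "ln parameter error",
                  title = "Key-parameter recovery by inertia scheme") +
    ggplot2::theme_minimal()
}

#' Plot the per-scheme fitness curves of a comparison
#'
#' @param comparison a `tc_comparison` tibble.
#' @return A ggplot of the global-best fitness against iteration, one line
#'   per seed, faceted by scheme (log fitness scale).
#' @export
plot_fitness_curves <- function(comparison) {
  stopifnot(inherits(comparison, "tc_comparison"))
  curves <- attr(comparison, "curves")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$k, y = .data$gbest_q,
                                       group = .data$seed)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration k", y = "global best fitness q") +
    ggplot2::theme_minimal()
}
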