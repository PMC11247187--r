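# broom-style accessors and plots.

#' Tidy a fitted CTMM
#'
#' One row per parameter with the estimate on the raw scale (baseline
#' intensities in events per unit time, coefficients as log hazard
#' ratios).  Pass `data` to append Wald standard errors and intervals.
#'
#' @param x A `ctmm_fit`.
#' @param data Optional panel data; when supplied the full [ctmm_ci()]
#'   report is returned.
#' @param ... Passed on to [ctmm_ci()].
#' @export
tidy.ctmm_fit <- function(x, data = NULL, ...) {
  if (!is.null(data)) return(ctmm_ci(data, x, ...))
  theta_raw <- params_to_theta(x$params_hat, scale = "raw")
  template <- x$template
  K <- length(template$q0)
  R <- length(template$covariate_names)
  tn <- transition_names(template$structure)
  if (template$mode == "transition_dependent") {
    type <- rep(c("q0", rep("beta", R)), K)
    transition <- rep(tn, each = 1 + R)
    covariate <- rep(c(NA_character_, template$covariate_names), K)
  } else {
    type <- c(rep("q0", K), rep("beta", R))
    transition <- c(tn, rep(NA_character_, R))
    covariate <- c(rep(NA_character_, K), template$covariate_names)
  }
  tibble::tibble(term = names(theta_raw), type = type,
                 transition = transition, covariate = covariate,
                 estimate = unname(theta_raw))
}

#' One-line fit summary
#'
#' @param x A `ctmm_fit`.
#' @param ... Unused.
#' @export
glance.ctmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_parameters = length(x$theta_hat),
                 M = x$M, n_intervals = x$n_intervals,
                 converged = x$converged, n_iters = x$n_iters,
                 restart_index = x$restart_index)
}

#' Tidy a Monte-Carlo report
#'
#' @param x A `ctmm_mc` from [run_scenario()].
#' @param level `"parameter"` for the per-parameter table or
#'   `"aggregate"` for class means.
#' @param ... Unused.
#' @export
tidy.ctmm_mc <- function(x, level = c("parameter", "aggregate"), ...) {
  level <- match.arg(level)
  if (level == "parameter") x$per_parameter else x$aggregate
}

#' Heatmap of a transition-probability (or empirical transition) matrix
#'
#' @param P Row-stochastic matrix, e.g. from [transition_probability()]
#'   or [empirical_transition_matrix()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_transition_matrix <- function(P, title = "Transition probabilities") {
  df <- as.data.frame(as.table(P))
  names(df) <- c("from", "to", "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = title, x = "to state", y = "from state",
                  fill = "P") +
    ggplot2::theme_minimal()
}

#' Plot the fitted transition-probability matrix
#'
#' @param object A `ctmm_fit`.
#' @param tau Elapsed time at which to evaluate `Exp(Q tau)`.
#' @param z Covariate vector (default: all zero, i.e. the baseline /
#'   reference profile).
#' @param ... Unused.
#' @export
autoplot.ctmm_fit <- function(object, tau = 1, z = NULL, ...) {
  p <- object$params_hat
  z <- z %||% rep(0, length(p$covariate_names))
  P <- transition_probability(build_intensity_matrix(p, z), tau)
  plot_transition_matrix(P, title = sprintf("Fitted P(tau = %g)", tau))
}

#' Forest plot of hazard ratios
#'
#' @param hr Output of [hazard_ratios()].
#' @return A ggplot object.
#' @export
plot_hazard_ratios <- function(hr) {
  ggplot2::ggplot(hr, ggplot2::aes(x = .data$transition, y = .data$hr)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "transition", y = "hazard ratio (95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
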