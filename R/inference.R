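# Standard errors, confidence intervals and hazard ratios from the
# observed information.
#
# Two Hessian constructions are offered: "pade" applies the block-matrix
# Frechet machinery twice (a 4S x 4S exponential per interval and
# transition), and "power_series" differentiates the truncation
# log (I + Q tau + (Q tau)^2 / 2) of the matrix exponential, which is
# cheaper for large state spaces but slightly understates the variance
# because the dropped terms carry curvature.

#' Hessian of the panel log-likelihood
#'
#' @param data Panel data.
#' @param object A `ctmm_fit` or a [ctmm_params()] at which to evaluate
#'   the Hessian.
#' @param method `"pade"` (exact, default) or `"power_series"`.
#' @param scale Parameter scale (defaults to the fit's optimization
#'   scale, or `"log_q0"` for a bare parameter set).
#' @param covariates Covariate column names.
#' @return A list of class `ctmm_hessian`: the symmetrized matrix `H`,
#'   the method, the scale, the count of excluded degenerate intervals,
#'   and a reciprocal condition number of `-H`.
#' @export
ctmm_hessian <- function(data, object, method = c("pade", "power_series"),
                         scale = NULL, covariates = NULL) {
  method <- match.arg(method)
  params <- if (inherits(object, "ctmm_fit")) object$params_hat else object
  scale <- scale %||% if (inherits(object, "ctmm_fit")) object$scale else "log_q0"
  pv <- panel_intervals(data, params$state_space,
                        covariates %||% default_covariates(params, data))
  ka <- kernel_args(params)
  fn <- if (method == "pade") cpp_panel_hessian_pade else cpp_panel_hessian_power
  res <- fn(ka$S, ka$allowed, ka$q0, ka$beta, ka$indep, scale == "log_q0",
            pv$from, pv$to, pv$tau, pv$Z, seq_len(pv$n) - 1L)
  if (res$n_excluded > 0)
    warn(sprintf("%d degenerate interval(s) excluded from the Hessian",
                 res$n_excluded))
  H <- res$H
  nm <- names(params_to_theta(params, scale = if (scale == "log_q0") "log_q0" else "raw"))
  dimnames(H) <- list(nm, nm)
  info <- -H
  rc <- tryCatch(rcond(info), error = function(e) NA_real_)
  ev_min <- tryCatch(min(eigen(info, symmetric = TRUE, only.values = TRUE)$values),
                     error = function(e) NA_real_)
  structure(list(H = H, method = method, scale = scale,
                 n_excluded = res$n_excluded, rcond = rc,
                 min_information_eigenvalue = ev_min,
                 positive_definite = isTRUE(ev_min > 0)),
            class = "ctmm_hessian")
}

#' @export
print.ctmm_hessian <- function(x, ...) {
  cat("<ctmm_hessian>", x$method, "on", x$scale, "scale |",
      nrow(x$H), "parameters | -H positive definite:", x$positive_definite, "\n")
  invisible(x)
}

# pseudo-inverse via SVD, for information matrices that fail to invert
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Wald confidence intervals and tests
#'
#' Standard errors are the square roots of the diagonal of the inverse
#' observed information (negative Hessian at the estimate), computed on
#' the optimization scale and mapped to the reporting scale by the delta
#' method: baseline intensities are reported as `exp(theta)` with
#' exp-transformed (asymmetric) intervals, coefficients as-is.
#'
#' @param data Panel data used for the fit.
#' @param fit A `ctmm_fit`.
#' @param method Hessian construction passed to [ctmm_hessian()].
#' @param level Confidence level (default 0.95).
#' @param hessian Optionally a precomputed [ctmm_hessian()] to reuse.
#' @return A tibble with one row per parameter: `term`, `type`
#'   (`"q0"`/`"beta"`), `transition`, `covariate`, `estimate` (raw
#'   scale), `std.error`, `statistic` (Wald z against 0), `conf.low`,
#'   `conf.high`, `reject` (at `1 - level`).
#' @export
ctmm_ci <- function(data, fit, method = c("pade", "power_series"),
                    level = 0.95, hessian = NULL) {
  method <- match.arg(method)
  hess <- hessian %||% ctmm_hessian(data, fit, method = method)
  info <- -hess$H
  V <- tryCatch({
    ch <- chol(info)
    chol2inv(ch)
  }, error = function(e) {
    warn("observed information is not positive definite; using a pseudo-inverse")
    pinv(info)
  })
  se <- sqrt(pmax(diag(V), 0))
  theta <- fit$theta_hat
  zq <- qnorm((1 + level) / 2)
  template <- fit$template
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
  is_q0 <- type == "q0"
  log_scale <- fit$scale == "log_q0"
  est <- ifelse(is_q0 & log_scale, exp(theta), theta)
  std <- ifelse(is_q0 & log_scale, est * se, se)  # delta method
  lo <- ifelse(is_q0 & log_scale, exp(theta - zq * se), theta - zq * se)
  hi <- ifelse(is_q0 & log_scale, exp(theta + zq * se), theta + zq * se)
  stat <- est / std
  tibble::tibble(term = names(theta), type = type, transition = transition,
                 covariate = covariate, estimate = unname(est),
                 std.error = unname(std), statistic = unname(stat),
                 conf.low = unname(lo), conf.high = unname(hi),
                 reject = abs(unname(stat)) > zq)
}

#' Transition-specific hazard ratios
#'
#' `exp(z_r * beta_ij,r)`: the multiplicative effect on the i -> j
#' intensity of setting covariate r to `at[r]` (on the analysis scale,
#' i.e. after any centering), with the confidence interval transformed
#' from the coefficient interval.
#'
#' @param ci A [ctmm_ci()] report.
#' @param at Named numeric vector of covariate values; defaults to 1 for
#'   every covariate (the per-unit hazard ratio).
#' @return Tibble: `transition`, `covariate`, `at`, `hr`, `conf.low`,
#'   `conf.high`.
#' @export
hazard_ratios <- function(ci, at = NULL) {
  b <- ci[ci$type == "beta", ]
  if (nrow(b) == 0) abort("no coefficients in this report")
  av <- rep(1, nrow(b))
  if (!is.null(at)) {
    if (is.null(names(at))) abort("`at` must be a named vector of covariate values")
    hit <- match(b$covariate, names(at))
    av[!is.na(hit)] <- at[hit[!is.na(hit)]]
  }
  lo <- exp(pmin(av * b$conf.low, av * b$conf.high))
  hi <- exp(pmax(av * b$conf.low, av * b$conf.high))
  tibble::tibble(transition = b$transition, covariate = b$covariate,
                 at = av, hr = exp(av * b$estimate),
                 conf.low = lo, conf.high = hi)
}
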