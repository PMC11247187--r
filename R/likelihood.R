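# Panel-data log-likelihood and exact score.
#
# Each observation interval contributes log (Exp(Q tau))_{s, s'} where Q
# is the generator built from the covariates observed at the interval
# START (carry-forward convention: the value measured at a visit governs
# the process until the next visit).  Derivatives of the matrix
# exponential come from block-matrix Frechet derivatives; see
# src/kernels.cpp for the adjoint trick that makes the full score one
# block exponential per interval.

#' Frechet derivative of the matrix exponential
#'
#' Directional derivative \eqn{\int_0^1 e^{uA} \dot A e^{(1-u)A} du} of
#' `Exp` at `A` in direction `Adot`, computed as the upper-right block of
#' `Exp([[A, Adot], [0, A]])`.
#'
#' @param A,Adot Square matrices of the same dimension.
#' @return Matrix of the same dimension as `A`.
#' @export
frechet_derivative_expm <- function(A, Adot) {
  A <- as.matrix(A); Adot <- as.matrix(Adot)
  if (!all(dim(A) == dim(Adot)) || nrow(A) != ncol(A))
    abort("`A` and `Adot` must be square matrices of equal dimension")
  cpp_frechet_expm(A, Adot)
}

#' Second directional derivative of the matrix exponential
#'
#' Evaluates \eqn{\partial^2 \mathrm{Exp}(A)} in directions `(E1, E2)`
#' including the curvature term `E12` (the second cross-derivative of
#' `A` with respect to the two underlying parameters; zero when `A` is
#' linear in them).  Computed as a block of the exponential of a
#' `4S x 4S` block upper-triangular matrix.
#'
#' @param A,E1,E2 Square matrices of equal dimension.
#' @param E12 Curvature direction; defaults to the zero matrix.
#' @export
second_frechet_expm <- function(A, E1, E2, E12 = NULL) {
  A <- as.matrix(A)
  if (is.null(E12)) E12 <- matrix(0, nrow(A), ncol(A))
  dims <- vapply(list(A, E1, E2, E12), function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != nrow(A)) || nrow(A) != ncol(A))
    abort("all blocks must be square matrices of equal dimension")
  cpp_second_frechet_expm(A, as.matrix(E1), as.matrix(E2), as.matrix(E12))
}

#' Derivative of the interval generator with respect to one parameter
#'
#' Returns \eqn{\partial (Q\tau) / \partial \theta_\ell} for the
#' interval with covariates `z` and elapsed time `tau`: the matrix with
#' the partial derivative at (i, j), its negation at (i, i) (preserving
#' zero row sums), and zeros elsewhere.
#'
#' @param params A [ctmm_params()].
#' @param z Covariate vector for the interval.
#' @param tau Elapsed time, `> 0`.
#' @param which Parameter index into the theta layout of
#'   [params_to_theta()].
#' @param scale Parameter scale the derivative is taken on.
#' @export
interval_dQ <- function(params, z, tau, which, scale = c("raw", "log_q0")) {
  scale <- match.arg(scale)
  S <- params$state_space$S
  idx <- structure_index(params$structure)
  K <- nrow(idx)
  R <- length(params$covariate_names)
  if (length(z) != R) abort("`z` has the wrong length")
  B <- if (params$mode == "transition_independent")
    matrix(params$beta[1, ], K, R, byrow = TRUE) else params$beta
  eta <- if (R == 0) rep(0, K) else as.numeric(B %*% z)
  out <- matrix(0, S, S)
  add_dir <- function(out, k, coef) {
    i <- idx[k, 1] + 1L; j <- idx[k, 2] + 1L
    out[i, j] <- out[i, j] + coef * tau
    out[i, i] <- out[i, i] - coef * tau
    out
  }
  if (params$mode == "transition_dependent") {
    k <- (which - 1L) %/% (1 + R) + 1L
    pos <- (which - 1L) %% (1 + R)
    if (k < 1 || k > K) abort("`which` is out of range")
    if (pos == 0) {
      coef <- if (scale == "log_q0") params$q0[[k]] * exp(eta[k]) else exp(eta[k])
    } else {
      coef <- params$q0[[k]] * z[pos] * exp(eta[k])
    }
    out <- add_dir(out, k, coef)
  } else {
    if (which < 1 || which > K + R) abort("`which` is out of range")
    if (which <= K) {
      coef <- if (scale == "log_q0") params$q0[[which]] * exp(eta[which]) else exp(eta[which])
      out <- add_dir(out, which, coef)
    } else {
      r <- which - K
      for (k in seq_len(K))
        out <- add_dir(out, k, params$q0[[k]] * z[r] * exp(eta[k]))
    }
  }
  out
}

# ---- panel plumbing ---------------------------------------------------------

covariate_columns <- function(data, covariates = NULL) {
  if (!is.null(covariates)) return(covariates)
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("subject_id", "time", "state"))
}

# flatten a long-format panel into per-interval arrays for the kernels
panel_intervals <- function(data, state_space, covariates = NULL) {
  for (col in c("subject_id", "time", "state"))
    if (!col %in% names(data)) abort(paste0("panel data needs a `", col, "` column"))
  if (anyNA(data$time) || anyNA(data$state)) abort("missing time or state values")
  covariates <- covariate_columns(data, covariates)
  ord <- order(match(data$subject_id, unique(data$subject_id)), data$time)
  data <- data[ord, ]
  sid <- match(data$subject_id, unique(data$subject_id))
  n <- nrow(data)
  same <- sid[-1] == sid[-n]
  tau <- diff(data$time)[same]
  if (any(tau <= 0)) {
    off <- data$subject_id[-1][same][tau <= 0]
    abort(paste0("non-increasing times within subject(s): ",
                 paste(unique(off), collapse = ", ")))
  }
  st <- state_index(state_space, data$state)
  from <- st[-n][same]
  to <- st[-1][same]
  Z <- as.matrix(data[covariates])[-n, , drop = FALSE][same, , drop = FALSE]
  if (anyNA(Z)) abort("missing covariate values (no imputation is done)")
  subj <- sid[-n][same] - 1L
  M <- length(unique(sid))
  si <- rep(list(integer()), M)  # subjects with < 2 visits contribute nothing
  grp <- split(seq_along(from) - 1L, subj)
  si[as.integer(names(grp)) + 1L] <- grp
  list(from = as.integer(from), to = as.integer(to), tau = as.numeric(tau),
       Z = Z, subj = as.integer(subj),
       subj_intervals = si, M = M, n = length(from),
       covariates = covariates)
}

#' Panel-data log-likelihood
#'
#' Sum over subjects and observation intervals of
#' \eqn{\log (\exp(Q_{mk}\tau_{mk}))_{s_{m(k-1)}, s_{mk}}}.  Transition
#' probabilities on observed transitions are floored at 1e-300 before
#' the log; any floored interval marks the evaluation as degenerate (see
#' the `n_floored` attribute), which typically means an observed
#' transition is structurally impossible under the model.
#'
#' @param data Long-format panel data: one row per (subject, visit) with
#'   columns `subject_id`, `time`, `state` and the covariate columns.
#' @param params A [ctmm_params()].
#' @param covariates Covariate column names; default: every numeric
#'   column except `subject_id`, `time`, `state`.
#' @return Scalar log-likelihood with attribute `n_floored`.
#' @export
ctmm_loglik <- function(data, params, covariates = NULL) {
  pv <- panel_intervals(data, params$state_space,
                        covariates %||% default_covariates(params, data))
  ka <- kernel_args(params)
  res <- cpp_panel_loglik(ka$S, ka$allowed, ka$q0, ka$beta, ka$indep, FALSE,
                          pv$from, pv$to, pv$tau, pv$Z,
                          seq_len(pv$n) - 1L)
  structure(res$loglik, n_floored = res$n_floored)
}

default_covariates <- function(params, data) {
  if (length(params$covariate_names) == 0) character() else params$covariate_names
}

#' Score (gradient) of the panel log-likelihood
#'
#' Exact gradient over the theta layout of [params_to_theta()]: per
#' interval the entry-wise ratio of the Frechet derivative of the matrix
#' exponential to the transition probability, summed over intervals and
#' subjects.  If an observed transition has zero probability the score
#' is undefined and a vector of `NaN` is returned with attribute
#' `degenerate = TRUE` so an optimizer can reject the point.
#'
#' @inheritParams ctmm_loglik
#' @param scale Differentiation scale: `"raw"` q0 or `"log_q0"`.
#' @return Named gradient vector with attributes `loglik`, `degenerate`.
#' @export
ctmm_score <- function(data, params, scale = c("raw", "log_q0"),
                       covariates = NULL) {
  scale <- match.arg(scale)
  pv <- panel_intervals(data, params$state_space,
                        covariates %||% default_covariates(params, data))
  ka <- kernel_args(params)
  res <- cpp_panel_score(ka$S, ka$allowed, ka$q0, ka$beta, ka$indep,
                         scale == "log_q0",
                         pv$from, pv$to, pv$tau, pv$Z, seq_len(pv$n) - 1L)
  g <- as.numeric(res$gradient)
  names(g) <- names(params_to_theta(params, scale = if (scale == "log_q0") "log_q0" else "raw"))
  structure(g, loglik = res$loglik, degenerate = res$degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
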