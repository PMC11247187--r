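# Parameter containers and the flat theta representation.
#
# theta layout (transition-major, deterministic):
#   transition-dependent:  [q0_1, beta_{1,1..R}, q0_2, beta_{2,1..R}, ...]
#   transition-independent: [q0_1, ..., q0_K, beta_1, ..., beta_R]
# On the "log_q0" scale the q0 slots hold log(q0) and the whole vector is
# unconstrained, which is the default scale for optimization.

#' Construct a CTMM parameter set
#'
#' Baseline transition intensities plus covariate coefficients for the
#' proportional-intensities model
#' \eqn{q_{ij}(z) = q^0_{ij} \exp(\sum_r z_r \beta_{ij,r})}.
#'
#' @param q0 Nonnegative baseline intensity per allowed transition, in
#'   events per unit time, ordered as in `structure`.
#' @param beta Coefficient matrix: `K x R` for the transition-dependent
#'   mode, or a length-`R` vector (one shared effect per covariate) for
#'   the transition-independent mode. May be `NULL` when `R = 0`.
#' @param structure A [transition_structure()].
#' @param mode `"transition_dependent"` or `"transition_independent"`.
#' @param covariate_names Character vector of length `R`.
#' @return An object of class `ctmm_params`.
#' @examples
#' ss <- state_space(0:1)
#' st <- transition_structure(0, 1, ss)
#' ctmm_params(q0 = 1, beta = matrix(log(2)), structure = st,
#'             covariate_names = "z1")
#' @export
ctmm_params <- function(q0, beta = NULL, structure,
                        mode = c("transition_dependent", "transition_independent"),
                        covariate_names = character()) {
  mode <- match.arg(mode)
  K <- nrow(structure)
  R <- length(covariate_names)
  if (length(q0) != K) abort("`q0` must have one entry per allowed transition")
  if (any(q0 < 0) || anyNA(q0)) abort("`q0` entries must be nonnegative and finite")
  if (R == 0) {
    beta <- matrix(0, ifelse(mode == "transition_dependent", K, 1), 0)
  } else if (mode == "transition_dependent") {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == c(K, R)))
      abort(sprintf("`beta` must be %d x %d in transition-dependent mode", K, R))
  } else {
    beta <- matrix(as.numeric(beta), nrow = 1)
    if (ncol(beta) != R)
      abort(sprintf("`beta` must have length %d in transition-independent mode", R))
  }
  if (!all(is.finite(beta))) abort("`beta` must be finite")
  structure(
    list(q0 = stats::setNames(as.numeric(q0), transition_names(structure)),
         beta = beta, mode = mode, covariate_names = covariate_names,
         structure = structure,
         state_space = attr(structure, "state_space")),
    class = "ctmm_params"
  )
}

#' @export
print.ctmm_params <- function(x, ...) {
  cat("<ctmm_params>", x$mode, "| K =", length(x$q0),
      "transitions | R =", length(x$covariate_names), "covariates\n")
  print(round(x$q0, 4))
  invisible(x)
}

n_parameters <- function(params) {
  K <- length(params$q0)
  R <- length(params$covariate_names)
  if (params$mode == "transition_dependent") K * (1 + R) else K + R
}

#' Flatten a parameter set to a theta vector
#'
#' @param params A [ctmm_params()] object.
#' @param scale `"log_q0"` (unconstrained; default) or `"raw"`.
#' @return Named numeric vector in the deterministic transition-major
#'   layout; round-trips losslessly through [theta_to_params()].
#' @export
params_to_theta <- function(params, scale = c("log_q0", "raw")) {
  scale <- match.arg(scale)
  K <- length(params$q0)
  R <- length(params$covariate_names)
  q0 <- if (scale == "log_q0") log(params$q0) else params$q0
  tn <- names(params$q0)
  if (params$mode == "transition_dependent") {
    blocks <- lapply(seq_len(K), function(k) {
      v <- c(q0[[k]], if (R > 0) params$beta[k, ] else numeric())
      names(v) <- c(paste0("q0(", tn[k], ")"),
                    if (R > 0) paste0("beta(", tn[k], ",", params$covariate_names, ")"))
      v
    })
    out <- unlist(blocks)
  } else {
    out <- c(stats::setNames(q0, paste0("q0(", tn, ")")),
             if (R > 0) stats::setNames(params$beta[1, ],
                                        paste0("beta(", params$covariate_names, ")")))
  }
  attr(out, "scale") <- scale
  out
}

#' Rebuild a parameter set from a theta vector
#'
#' @param theta Numeric vector in the layout produced by
#'   [params_to_theta()].
#' @param template A `ctmm_params` supplying structure, mode and
#'   covariate names.
#' @inheritParams params_to_theta
#' @export
theta_to_params <- function(theta, template, scale = c("log_q0", "raw")) {
  scale <- match.arg(scale)
  K <- length(template$q0)
  R <- length(template$covariate_names)
  if (length(theta) != n_parameters(template))
    abort("`theta` has the wrong length for this model")
  if (template$mode == "transition_dependent") {
    m <- matrix(theta, nrow = K, ncol = 1 + R, byrow = TRUE)
    q0 <- m[, 1]
    beta <- if (R > 0) m[, -1, drop = FALSE] else NULL
  } else {
    q0 <- theta[seq_len(K)]
    beta <- if (R > 0) theta[K + seq_len(R)] else NULL
  }
  if (scale == "log_q0") q0 <- exp(q0)
  ctmm_params(q0 = q0, beta = beta, structure = template$structure,
              mode = template$mode, covariate_names = template$covariate_names)
}
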