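# Generator construction, transition probabilities and the stationary
# law.  Dense S x S matrices throughout: the state spaces this package
# targets are small (S <= ~9) and structural zeros are enforced by
# masking, not sparse storage.

# kernel argument bundle shared by the compiled likelihood routines
kernel_args <- function(params) {
  list(S = params$state_space$S,
       allowed = structure_index(params$structure),
       q0 = unname(params$q0),
       beta = params$beta,
       indep = params$mode == "transition_independent")
}

#' Build the covariate-modulated intensity matrix
#'
#' For each allowed transition (i, j) the intensity is
#' \eqn{q_{ij} = q^0_{ij} \exp(\sum_r z_r \beta_{ij,r})}; disallowed
#' off-diagonals are structurally zero, and the diagonal is the negative
#' row sum, so every row sums to zero.
#'
#' @param params A [ctmm_params()] object.
#' @param z Covariate vector of length `R` (use `numeric(0)` or the
#'   default for a covariate-free model).
#' @return The `S x S` generator matrix (states ordered as in the state
#'   space), in events per unit time.
#' @examples
#' ss <- state_space(0:1)
#' st <- transition_structure(0, 1, ss)
#' p <- ctmm_params(1, matrix(log(2)), st, covariate_names = "z")
#' build_intensity_matrix(p, z = 1)  # q01 = 2
#' @export
build_intensity_matrix <- function(params, z = numeric()) {
  R <- length(params$covariate_names)
  if (length(z) != R)
    abort(sprintf("`z` must have length %d to match the covariates", R))
  S <- params$state_space$S
  idx <- structure_index(params$structure)
  eta <- if (R == 0) rep(0, nrow(idx)) else {
    B <- if (params$mode == "transition_independent")
      matrix(params$beta[1, ], nrow(idx), R, byrow = TRUE) else params$beta
    as.numeric(B %*% z)
  }
  q <- unname(params$q0) * exp(eta)
  Q <- matrix(0, S, S, dimnames = list(params$state_space$labels,
                                       params$state_space$labels))
  for (k in seq_len(nrow(idx))) {
    Q[idx[k, 1] + 1L, idx[k, 2] + 1L] <- Q[idx[k, 1] + 1L, idx[k, 2] + 1L] + q[k]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix over an elapsed time
#'
#' Solves the Kolmogorov relation \eqn{P(\tau) = \exp(Q\tau)} by
#' scaling-and-squaring with a Pade approximant.  Tiny negative entries
#' from roundoff (below 1e-12 in magnitude) are clipped to zero.
#'
#' @param Q Generator matrix (rows summing to zero).
#' @param tau Elapsed time, `tau >= 0`.
#' @return Row-stochastic `S x S` matrix.
#' @export
transition_probability <- function(Q, tau) {
  if (tau < 0) abort("`tau` must be nonnegative")
  validate_generator(Q)
  P <- cpp_expm(Q * tau)
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

validate_generator <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) abort("`Q` must be square")
  off <- Q - diag(diag(Q))
  if (any(off < -1e-12)) abort("off-diagonal intensities must be nonnegative")
  if (max(abs(rowSums(Q))) > tol) abort("generator rows must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a generator
#'
#' Solves \eqn{\pi^T Q = 0}, \eqn{\sum_i \pi_i = 1}.  For reducible
#' chains the solution is supported on a recurrent class and a warning
#' reports the non-uniqueness.
#'
#' @param Q Generator matrix.
#' @return Probability vector of length `S`.
#' @examples
#' Q <- matrix(c(-1, 1, 3, -3), 2, 2, byrow = TRUE)
#' stationary_distribution(Q)  # (0.75, 0.25)
#' @export
stationary_distribution <- function(Q) {
  validate_generator(Q)
  S <- nrow(Q)
  ev <- eigen(t(Q))
  n_null <- sum(abs(ev$values) < 1e-9)
  if (n_null > 1) {
    # reducible chain with several recurrent classes: every convex
    # combination of class solutions satisfies pi'Q = 0
    warn("generator is reducible: stationary distribution is not unique; returning one recurrent-class solution")
    V <- Re(ev$vectors[, abs(ev$values) < 1e-9, drop = FALSE])
    signed <- apply(V, 2, function(v) all(v >= -1e-10) || all(v <= 1e-10))
    v <- if (any(signed)) abs(V[, which(signed)[1]]) else pmax(V[, 1], 0)
    return(stats::setNames(v / sum(v), rownames(Q)))
  }
  # append the normalization row to Q^T and solve the least-squares system
  M <- rbind(t(Q), rep(1, S))
  b <- c(rep(0, S), 1)
  pi_hat <- tryCatch(
    as.numeric(qr.solve(M, b)),
    error = function(e) abort("singular stationary solve: generator degenerate")
  )
  if (any(pi_hat < -1e-8)) abort("stationary solve produced negative mass")
  pi_hat[pi_hat < 0] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  if (max(abs(pi_hat %*% Q)) > 1e-8 && n_null <= 1)
    abort("stationary solve failed to satisfy pi'Q = 0")
  stats::setNames(pi_hat, rownames(Q))
}
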