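# Shared fixtures: all inputs are generated in code.

# random irreducible generator with unit-scale rates
rand_generator <- function(S, scale = 1) {
  Q <- matrix(runif(S * S, 0.1, 1), S, S) * scale
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# truncated power series oracle for Exp(A)
series_expm <- function(A, nterm = 40) {
  S <- nrow(A)
  out <- diag(S)
  term <- diag(S)
  for (l in seq_len(nterm)) {
    term <- term %*% A / l
    out <- out + term
  }
  out
}

# central finite-difference directional derivative of Exp
fd_frechet <- function(A, E, h = 1e-6) {
  (sctmm:::cpp_expm(A + h * E) - sctmm:::cpp_expm(A - h * E)) / (2 * h)
}

# second-order central cross difference of Exp in directions (E1, E2)
fd_second_frechet <- function(A, E1, E2, h = 1e-4) {
  (sctmm:::cpp_expm(A + h * E1 + h * E2) - sctmm:::cpp_expm(A + h * E1 - h * E2) -
   sctmm:::cpp_expm(A - h * E1 + h * E2) + sctmm:::cpp_expm(A - h * E1 - h * E2)) /
    (4 * h^2)
}

# two-state chain with both directions allowed
two_state <- function(q01 = 0.5, q10 = 0.3, beta = NULL, covariate_names = character()) {
  ss <- state_space(0:1)
  st <- all_transitions(ss)
  ctmm_params(c(q01, q10), beta, st, covariate_names = covariate_names)
}

# one-way absorbing two-state chain 0 -> 1
one_way <- function(a = 0.5) {
  ss <- state_space(0:1)
  st <- transition_structure(0, 1, ss)
  ctmm_params(a, structure = st)
}

# small three-state model with all transitions and R covariates
three_state <- function(R = 1, beta_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ss <- state_space(0:2)
  st <- all_transitions(ss)
  covn <- if (R > 0) paste0("z", seq_len(R)) else character()
  beta <- if (R > 0) matrix(rnorm(6 * R, 0, beta_sd), 6, R) else NULL
  ctmm_params(runif(6, 0.2, 0.8), beta, st, covariate_names = covn)
}

# hand-built panel: one subject per row-run of (times, states)
panel_from <- function(times, states, subject_id = 1, z = NULL) {
  out <- tibble::tibble(subject_id = subject_id, time = times, state = states)
  if (!is.null(z)) for (nm in names(z)) out[[nm]] <- z[[nm]]
  out
}

# numerical gradient of the panel log-likelihood
fd_score <- function(dat, params, scale = "raw", h = 1e-6) {
  th <- params_to_theta(params, scale)
  vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (as.numeric(ctmm_loglik(dat, theta_to_params(tp, params, scale))) -
     as.numeric(ctmm_loglik(dat, theta_to_params(tm, params, scale)))) / (2 * h)
  }, numeric(1))
}
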