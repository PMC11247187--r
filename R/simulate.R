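# Exact trajectory simulation for the covariate-modulated CTMM.
#
# The latent path is simulated exactly (Gillespie style): sojourns are
# exponential with the current total exit rate and the jump target
# follows the embedded chain q_ij / (-q_ii).  The initial state is
# drawn from the stationary law of the generator at the subject's
# initial covariates.  What is OBSERVED is a separate question:
#
#   observe = "scheduled"  (default): the state is recorded at regular
#     assessment visits only; transition times stay latent, which is
#     exactly the interval censoring the panel likelihood is built for.
#   observe = "all_events": visits at every jump time as well.  Exact
#     jump times make the observation process informative and bias
#     panel-likelihood rate estimates upward; this mode exists for
#     distributional checks on the latent path and for comparison.
#
# Covariates are redrawn at every OBSERVED visit (time-fixed ones are
# drawn once per subject) and the generator is rebuilt from the new
# values for the remaining sojourn -- piecewise-constant intensities,
# consistent with the likelihood's carry-forward convention.  By
# memorylessness the residual sojourn is simply redrawn.

#' Simulation settings
#'
#' @param M Number of subjects.
#' @param params True [ctmm_params()] (baseline intensities plus
#'   coefficients).
#' @param t_max Follow-up horizon in time units (default 15, a long
#'   observational cohort).
#' @param dummy_interval Spacing of scheduled assessment visits
#'   (default 0.5, i.e. 6-monthly when time is in years, giving 31
#'   visits over 15 years). `Inf` disables scheduled visits (only
#'   meaningful with `observe = "all_events"`).
#' @param covariate_law Function `(n)` drawing one visit's covariate
#'   values; the default is Uniform(0,1) centered at zero.
#' @param covariate_fixed Logical vector (length R): covariates drawn
#'   once per subject (time-fixed) instead of redrawn at every visit.
#' @param observe `"scheduled"` records the state at scheduled visits
#'   only (interval censoring; default); `"all_events"` additionally
#'   emits an observation at every transition time.
#' @param next_state `"embedded"` draws jumps from the embedded chain
#'   q_ij/(-q_ii) (default, the exact law of the jump target);
#'   `"ptau"` draws from the row of Exp(Q w) at the sojourn length w,
#'   kept for comparison.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M, params, t_max = 15, dummy_interval = 0.5,
                       covariate_law = function(n) runif(n) - 0.5,
                       covariate_fixed = NULL,
                       observe = c("scheduled", "all_events"),
                       next_state = c("embedded", "ptau")) {
  stopifnot(M >= 1, t_max > 0, dummy_interval > 0)
  R <- length(params$covariate_names)
  covariate_fixed <- covariate_fixed %||% rep(FALSE, R)
  stopifnot(length(covariate_fixed) == R)
  structure(list(M = M, params = params, t_max = t_max,
                 dummy_interval = dummy_interval,
                 covariate_law = covariate_law,
                 covariate_fixed = covariate_fixed,
                 observe = match.arg(observe),
                 next_state = match.arg(next_state)),
            class = "sim_config")
}

draw_z <- function(config, z_fixed) {
  R <- length(config$params$covariate_names)
  if (R == 0) return(numeric())
  z <- config$covariate_law(R)
  z[config$covariate_fixed] <- z_fixed[config$covariate_fixed]
  z
}

# intensities per allowed transition at covariates z
rates_at <- function(params, idx, z) {
  R <- length(params$covariate_names)
  eta <- if (R == 0) rep(0, nrow(idx)) else {
    B <- if (params$mode == "transition_independent")
      matrix(params$beta[1, ], nrow(idx), R, byrow = TRUE) else params$beta
    as.numeric(B %*% z)
  }
  unname(params$q0) * exp(eta)
}

draw_next_state <- function(config, idx, q, s, z, w) {
  if (config$next_state == "embedded") {
    out <- idx[, 1] == s
    targets <- idx[out, 2]
    targets[sample.int(length(targets), 1, prob = q[out])]
  } else {
    # alternative reading: next state from the row of Exp(Q w)
    Qz <- build_intensity_matrix(config$params, z)
    p <- cpp_expm(Qz * w)
    sample.int(nrow(p), 1, prob = pmax(p[s + 1L, ], 0)) - 1L
  }
}

#' Simulate one subject trajectory
#'
#' @param config A [sim_config()].
#' @param subject_id Identifier stored in the output rows.
#' @return Tibble of time-ordered observations (`subject_id`, `time`,
#'   `state`, covariate columns), all times in `[0, t_max]`.
#' @export
simulate_subject <- function(config, subject_id = 1L) {
  params <- config$params
  sspace <- params$state_space
  idx <- structure_index(params$structure)
  R <- length(params$covariate_names)
  z_fixed <- if (R > 0) config$covariate_law(R) else numeric()
  z <- draw_z(config, z_fixed)
  Q0 <- build_intensity_matrix(params, z)
  pi0 <- suppressWarnings(stationary_distribution(Q0))
  s <- sample.int(sspace$S, 1, prob = pi0) - 1L  # internal 0-based
  rows <- list()
  n_rows <- 0L
  emit <- function(t, s, z) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- c(t, s, z)
  }
  t <- 0
  emit(t, s, z)
  next_visit <- config$dummy_interval
  all_events <- config$observe == "all_events"
  repeat {
    q <- rates_at(params, idx, z)
    rate <- sum(q[idx[, 1] == s])
    jump_t <- if (rate > 0) t + rexp(1, rate) else Inf
    if (!all_events) {
      if (next_visit > config$t_max) break
      if (jump_t < next_visit) {
        # latent jump before the next visit: advance the path silently
        s <- draw_next_state(config, idx, q, s, z, jump_t - t)
        t <- jump_t
        next
      }
      t <- next_visit
      z <- draw_z(config, z_fixed)
      emit(t, s, z)
      next_visit <- t + config$dummy_interval
      next  # residual sojourn redrawn under the (possibly new) generator
    }
    # all_events mode: scheduled visit first if it precedes the jump
    if (jump_t >= next_visit && next_visit <= config$t_max) {
      t <- next_visit
      z <- draw_z(config, z_fixed)
      emit(t, s, z)
      next_visit <- t + config$dummy_interval
      next
    }
    if (jump_t > config$t_max) break  # unobserved final jump: truncate
    s <- draw_next_state(config, idx, q, s, z, jump_t - t)
    t <- jump_t
    z <- draw_z(config, z_fixed)
    emit(t, s, z)
    next_visit <- t + config$dummy_interval
  }
  m <- do.call(rbind, rows[seq_len(n_rows)])
  out <- tibble::tibble(subject_id = subject_id, time = m[, 1],
                        state = sspace$labels[m[, 2] + 1L])
  if (R > 0) for (r in seq_len(R))
    out[[params$covariate_names[r]]] <- m[, 2 + r]
  out
}

#' Simulate a panel dataset
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; a fixed seed makes the dataset
#'   reproducible.
#' @return Long-format panel tibble of `M` independent trajectories.
#' @examples
#' ss <- state_space(0:1)
#' truth <- ctmm_params(c(0.5, 0.5), structure = all_transitions(ss))
#' simulate_panel(sim_config(M = 3, params = truth, t_max = 2), seed = 1)
#' @export
simulate_panel <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(config$M), function(m)
    simulate_subject(config, subject_id = m)))
}
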