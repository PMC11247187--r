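# Mini-batch stochastic gradient ascent on the panel log-likelihood.
#
# One update is
#   theta_{d+1} = theta_d + lambda_{d+1} (M/|B_d|) sum_{m in B_d} grad loglik_m
# with decreasing learning rate lambda_{d+1} = lr_scale * (d+1)^(-lr_exponent).
# Optimization runs on the log-q0 scale by default so that a large step
# can never produce a negative intensity.  The likelihood is not
# globally concave, hence restarts with random initial values; the
# restart with the highest full-data log-likelihood wins.

#' Optimizer settings
#'
#' @param batch_size Subjects per mini-batch (capped at M; with
#'   `batch_size >= M` every step is a full deterministic gradient step).
#' @param lr_exponent Learning-rate decay exponent; the rate at step `d`
#'   is `lr_scale * (d+1)^(-lr_exponent)`. `0` gives a constant rate.
#' @param lr_scale Base learning rate. The default `NULL` probes it at
#'   each restart's initialization: the log-likelihood is evaluated
#'   along the initial gradient ray on a subject subsample and the most
#'   profitable step size wins.  This adapts the rate to the local
#'   curvature, which varies strongly with data volume; an explicit
#'   value skips the probe.
#' @param max_iters Maximum SGD iterations per restart.
#' @param tol Convergence threshold: sup-norm of the parameter change,
#'   averaged over the last `tol_window` iterations (raw per-step
#'   changes oscillate under stochastic gradients).
#' @param tol_window Number of trailing steps averaged for `tol`.
#' @param restarts Number of random restarts. 20 is a pragmatic default
#'   for moderate problems; 1000-5000 is advisable for large models
#'   where saddle points and local optima are a real risk.
#' @param init_policy `"distance_decay_normal"` (q0 drawn from the
#'   positive part of Normal(1/|i-j|, 1/|i-j|), beta from Uniform(-1,1)),
#'   `"warmstart_subsample"` (deterministic full-gradient fit on a
#'   subsample seeds all restarts), or `"user"` (supply `init=` to
#'   [ctmm_fit()]).
#' @param sampling `"without_replacement"` (epoch-wise shuffling,
#'   default) or `"with_replacement"`.
#' @param scale Optimization scale for the baseline intensities.
#' @param max_retry Non-finite step handling: halve the rate and retry
#'   this many times, then skip the batch.
#' @param warmstart_size Subjects used by the warmstart policy.
#' @param warmstart_iters Full-gradient iterations of the warmstart fit.
#' @param trace_every Record the validation-batch log-likelihood every
#'   this many iterations (0 = never; step norms are always traced).
#' @param precondition Rescale the gradient by the inverse absolute
#'   diagonal of a subsample Hessian computed once at initialization.
#'   This is ordinary SGD in a linearly rescaled parameterization; it
#'   equalizes the information carried by rate and coefficient
#'   coordinates and speeds convergence considerably.
#' @return A list of class `ctmm_control`.
#' @export
ctmm_control <- function(batch_size = 500, lr_exponent = 0.6, lr_scale = NULL,
                         max_iters = 500, tol = 1e-6, tol_window = 5,
                         restarts = 20,
                         init_policy = c("distance_decay_normal",
                                         "warmstart_subsample", "user"),
                         sampling = c("without_replacement", "with_replacement"),
                         scale = c("log_q0", "raw"),
                         max_retry = 5, warmstart_size = 500,
                         warmstart_iters = 200, trace_every = 0,
                         precondition = TRUE) {
  stopifnot(batch_size >= 1, tol > 0, restarts >= 1, max_iters >= 1,
            lr_exponent >= 0, tol_window >= 1)
  structure(list(batch_size = batch_size, lr_exponent = lr_exponent,
                 lr_scale = lr_scale, max_iters = max_iters, tol = tol,
                 tol_window = tol_window, restarts = restarts,
                 init_policy = match.arg(init_policy),
                 sampling = match.arg(sampling), scale = match.arg(scale),
                 max_retry = max_retry, warmstart_size = warmstart_size,
                 warmstart_iters = warmstart_iters, trace_every = trace_every,
                 precondition = precondition),
            class = "ctmm_control")
}

#' Learning-rate schedule
#'
#' `lr_scale * (d+1)^(-lr_exponent)` for iteration index `d >= 0`; with
#' the defaults the sequence starts at 1 and decays polynomially.
#'
#' @param d Iteration index (0-based).
#' @param lr_exponent,lr_scale Schedule parameters.
#' @export
learning_rate <- function(d, lr_exponent = 0.6, lr_scale = 1) {
  stopifnot(all(d >= 0))
  lr_scale * (d + 1)^(-lr_exponent)
}

#' Draw initial parameters
#'
#' The `distance_decay_normal` policy draws each baseline intensity from
#' the positive part of Normal(1/|i-j|, 1/|i-j|) (index distance of the
#' transition; nearby states start faster) and each coefficient from
#' Uniform(-1, 1).  The `warmstart_subsample` policy runs a
#' deterministic full-gradient fit on a subject subsample and returns
#' its estimate.
#'
#' @param policy Initialization policy.
#' @param template A [ctmm_params()] giving structure, mode, covariates.
#' @param data Panel data (required for `warmstart_subsample`).
#' @param control A [ctmm_control()].
#' @return Theta vector on `control$scale`.
#' @export
init_parameters <- function(policy = c("distance_decay_normal",
                                       "warmstart_subsample", "user"),
                            template, data = NULL,
                            control = ctmm_control()) {
  policy <- match.arg(policy)
  if (policy == "user")
    abort("policy 'user' needs an explicit `init` vector passed to ctmm_fit()")
  idx <- structure_index(template$structure)
  K <- nrow(idx)
  R <- length(template$covariate_names)
  if (policy == "distance_decay_normal") {
    dist <- pmax(abs(idx[, 1] - idx[, 2]), 1L)
    q0 <- vapply(dist, function(d) {
      repeat {
        x <- rnorm(1, mean = 1 / d, sd = 1 / d)
        if (x > 0) return(x)
      }
    }, numeric(1))
    nb <- if (template$mode == "transition_dependent") K * R else R
    beta <- runif(nb, -1, 1)
    p <- ctmm_params(q0,
                     if (R > 0) matrix(beta, ncol = R, byrow = TRUE) else NULL,
                     template$structure, template$mode, template$covariate_names)
    return(params_to_theta(p, scale = control$scale))
  }
  # warmstart: deterministic full-gradient ascent on a subsample
  if (is.null(data)) abort("warmstart_subsample needs `data`")
  pv <- panel_intervals(data, template$state_space,
                        default_covariates(template, data))
  keep <- sort(sample.int(pv$M, min(control$warmstart_size, pv$M)))
  sub_ctrl <- control
  sub_ctrl$batch_size <- length(keep)
  sub_ctrl$max_iters <- control$warmstart_iters
  theta0 <- init_parameters("distance_decay_normal", template, control = control)
  run <- run_sgd(pv, template, theta0, sub_ctrl, subjects = keep)
  run$theta
}

# theta (fitting scale) -> kernel-ready raw parameter pieces
theta_pieces <- function(theta, template, scale) {
  p <- theta_to_params(theta, template, scale = scale)
  list(q0 = unname(p$q0), beta = p$beta)
}

# Fixed diagonal preconditioner: inverse absolute diagonal of a
# subsample Hessian at the initial point.  This is still plain SGD --
# just run in a linearly rescaled parameterization -- but it equalizes
# the very different information carried by baseline-rate and
# coefficient coordinates, without which a single global learning rate
# crawls on ill-conditioned problems.
precondition_diag <- function(pv, template, theta0, control, sub) {
  P <- n_parameters(template)
  idx <- unlist(pv$subj_intervals[sub], use.names = FALSE)
  if (length(idx) == 0) return(rep(1, P))
  ka <- kernel_args(template)
  pieces <- theta_pieces(theta0, template, control$scale)
  res <- tryCatch(
    cpp_panel_hessian_pade(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep,
                           control$scale == "log_q0", pv$from, pv$to, pv$tau,
                           pv$Z, idx),
    error = function(e) NULL)
  if (is.null(res)) return(rep(1, P))
  h <- abs(diag(res$H))
  if (!all(is.finite(h)) || max(h) <= 0) return(rep(1, P))
  h <- pmax(h, 1e-3 * max(h))       # guard near-uninformed coordinates
  (max(h) / h)                       # unit scale for the stiffest coordinate
}

# Armijo-style probe for the base learning rate: walk the initial
# (preconditioned) full-data-scale gradient ray on a subject subsample
# and keep the step size that gains the most log-likelihood.  The
# probed rate adapts to the local curvature, which varies strongly with
# data volume and parameter scale.
auto_lr_scale <- function(pv, template, theta0, control, precond, sub) {
  ka <- kernel_args(template)
  idx <- unlist(pv$subj_intervals[sub], use.names = FALSE)
  fallback <- 1 / max(1, pv$n)
  if (length(idx) == 0) return(fallback)
  log_scale <- control$scale == "log_q0"
  pieces <- theta_pieces(theta0, template, control$scale)
  sc <- cpp_panel_score(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep,
                        log_scale, pv$from, pv$to, pv$tau, pv$Z, idx)
  g <- as.numeric(sc$gradient)
  if (!all(is.finite(g))) return(fallback)
  d <- (pv$M / length(sub)) * precond * g  # the magnitude an actual update uses
  ll_at <- function(theta) {
    pieces <- theta_pieces(theta, template, control$scale)
    cpp_panel_loglik(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep, FALSE,
                     pv$from, pv$to, pv$tau, pv$Z, idx)$loglik
  }
  base <- ll_at(theta0)
  best_lr <- fallback
  best_ll <- base
  for (j in seq(-20, 4)) {
    lr <- 2^j
    cand <- theta0 + lr * d
    if (max(abs(cand)) > 50) break  # exp overflow territory
    ll <- ll_at(cand)
    if (is.finite(ll) && ll > best_ll) {
      best_ll <- ll
      best_lr <- lr
    } else if (best_ll > base && is.finite(ll) && ll < best_ll) {
      break  # past the peak along the ray
    }
  }
  best_lr
}

# one epoch-aware SGD run; `subjects` restricts to a subsample (1-based)
run_sgd <- function(pv, template, theta0, control, subjects = NULL) {
  subjects <- subjects %||% seq_len(pv$M)
  M <- length(subjects)
  ka <- kernel_args(template)
  sub <- subjects[seq_len(min(150L, M))]
  precond <- if (isTRUE(control$precondition))
    precondition_diag(pv, template, theta0, control, sub) else
    rep(1, n_parameters(template))
  lr_scale <- control$lr_scale %||%
    auto_lr_scale(pv, template, theta0, control, precond, sub)
  bsz <- min(control$batch_size, M)
  theta <- theta0
  log_scale <- control$scale == "log_q0"
  changes <- rep(NA_real_, control$tol_window)
  trace <- vector("list", control$max_iters)
  val_subj <- subjects[seq_len(min(100, M))]
  val_idx <- unlist(pv$subj_intervals[val_subj], use.names = FALSE)
  d <- 0L
  converged <- FALSE
  pool <- integer()
  # progress monitor: subsample log-likelihood every check_every steps;
  # on deterioration restore the best visited point and halve the rate
  check_every <- 20L
  mon_idx <- unlist(pv$subj_intervals[sub], use.names = FALSE)
  mon_ll <- function(th) {
    pieces <- theta_pieces(th, template, control$scale)
    cpp_panel_loglik(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep, FALSE,
                     pv$from, pv$to, pv$tau, pv$Z, mon_idx)$loglik
  }
  best_theta <- theta
  best_mon <- mon_ll(theta)
  while (d < control$max_iters) {
    if (control$sampling == "with_replacement") {
      batch <- sample(subjects, bsz, replace = TRUE)
    } else {
      if (length(pool) < bsz) pool <- sample(subjects)  # new epoch
      batch <- pool[seq_len(bsz)]
      pool <- pool[-seq_len(bsz)]
    }
    idx <- unlist(pv$subj_intervals[batch], use.names = FALSE)
    if (length(idx) == 0) { d <- d + 1L; next }
    pieces <- theta_pieces(theta, template, control$scale)
    sc <- cpp_panel_score(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep,
                          log_scale, pv$from, pv$to, pv$tau, pv$Z, idx)
    g <- as.numeric(sc$gradient)
    lr <- learning_rate(d, control$lr_exponent, lr_scale)
    accepted <- FALSE
    for (retry in 0:control$max_retry) {
      if (!all(is.finite(g))) break
      step <- lr * (M / bsz) * precond * g
      cand <- theta + step
      if (all(is.finite(cand))) {
        # reject steps into degenerate regions (non-finite likelihood)
        theta <- cand
        changes <- c(changes[-1], max(abs(step)))
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    val_ll <- NA_real_
    if (control$trace_every > 0 && (d %% control$trace_every == 0)) {
      pieces <- theta_pieces(theta, template, control$scale)
      val_ll <- cpp_panel_loglik(ka$S, ka$allowed, pieces$q0, pieces$beta,
                                 ka$indep, FALSE, pv$from, pv$to, pv$tau,
                                 pv$Z, val_idx)$loglik
    }
    d <- d + 1L
    trace[[d]] <- c(iter = d, step_norm = if (accepted) changes[control$tol_window] else NA_real_,
                    val_loglik = val_ll)
    if (d %% check_every == 0L) {
      cur <- mon_ll(theta)
      if (!is.finite(cur) || cur < best_mon - 1e-8) {
        theta <- best_theta
        lr_scale <- lr_scale / 2
      } else {
        best_mon <- cur
        best_theta <- theta
      }
    }
    if (is.null(control$lr_scale) && d %% 50L == 0L && d < control$max_iters) {
      # re-anchor the decaying schedule: the profitable step size changes
      # along the path as the local curvature does
      probed <- auto_lr_scale(pv, template, theta, control, precond, sub)
      lr_scale <- probed * (d + 1)^(control$lr_exponent)
    }
    if (all(is.finite(changes)) && mean(changes) < control$tol) {
      converged <- TRUE
      break
    }
  }
  cur <- mon_ll(theta)
  if (is.finite(cur) && cur > best_mon) best_theta <- theta
  theta <- best_theta
  tr <- tibble::as_tibble(do.call(rbind, trace[seq_len(d)]))
  list(theta = theta, n_iters = d, converged = converged, trace = tr)
}

#' One mini-batch stochastic gradient step
#'
#' Applies a single ascent update
#' `theta + lr(d) * (M/|B|) * sum_{m in B} grad loglik_m(theta)` for the
#' subjects in `batch`; mainly useful for inspecting the optimizer.
#'
#' @param data Panel data.
#' @param theta Current parameter vector on `control$scale`.
#' @param template A [ctmm_params()] defining the model.
#' @param batch Vector of subject ids forming the mini-batch.
#' @param d Iteration index (0-based) for the learning-rate schedule.
#' @param control A [ctmm_control()].
#' @param M Total number of subjects the gradient is rescaled to;
#'   defaults to the number of subjects in `data`.
#' @export
minibatch_step <- function(data, theta, template, batch, d,
                           control = ctmm_control(), M = NULL) {
  pv <- panel_intervals(data, template$state_space,
                        default_covariates(template, data))
  M <- M %||% pv$M
  ids <- match(batch, unique(data$subject_id))
  if (anyNA(ids)) abort("`batch` contains unknown subject ids")
  idx <- unlist(pv$subj_intervals[ids], use.names = FALSE)
  ka <- kernel_args(template)
  pieces <- theta_pieces(theta, template, control$scale)
  sc <- cpp_panel_score(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep,
                        control$scale == "log_q0",
                        pv$from, pv$to, pv$tau, pv$Z, idx)
  g <- as.numeric(sc$gradient)
  if (!all(is.finite(g))) abort("non-finite gradient on this batch")
  lr_scale <- control$lr_scale %||% (1 / max(1, pv$n))
  theta + learning_rate(d, control$lr_exponent, lr_scale) *
    (M / length(ids)) * g
}

#' Fit a CTMM to panel data
#'
#' Maximizes the interval-censored panel likelihood by mini-batch
#' stochastic gradient ascent with restarts; the restart reaching the
#' highest full-data log-likelihood supplies the estimate.
#'
#' @param data Long-format panel data (`subject_id`, `time`, `state`,
#'   covariate columns).
#' @param structure A [transition_structure()] of modelled transitions.
#' @param mode Covariate model: transition-dependent (one coefficient
#'   per transition and covariate) or transition-independent (shared
#'   coefficients).
#' @param covariates Covariate column names (default: all numeric
#'   columns except the id/time/state columns).
#' @param control A [ctmm_control()].
#' @param init Optional user initialization: a theta vector on
#'   `control$scale`, used by every restart (policy `"user"`).
#' @param seed Optional integer seed making the whole fit reproducible.
#' @return A `ctmm_fit` object; see [tidy.ctmm_fit()] and
#'   [glance.ctmm_fit()] for tidy accessors.
#' @examples
#' ss <- state_space(0:1)
#' st <- all_transitions(ss)
#' truth <- ctmm_params(c(0.4, 0.6), structure = st)
#' dat <- simulate_panel(sim_config(M = 50, params = truth, t_max = 4), seed = 1)
#' fit <- ctmm_fit(dat, st, control = ctmm_control(restarts = 2, max_iters = 60),
#'                 seed = 1)
#' glance(fit)
#' @export
ctmm_fit <- function(data, structure,
                     mode = c("transition_dependent", "transition_independent"),
                     covariates = NULL, control = ctmm_control(),
                     init = NULL, seed = NULL) {
  mode <- match.arg(mode)
  sspace <- attr(structure, "state_space")
  covariates <- covariates %||% covariate_columns(data)
  R <- length(covariates)
  K <- nrow(structure)
  template <- ctmm_params(rep(1, K),
                          if (R > 0) matrix(0, if (mode == "transition_dependent") K else 1, R) else NULL,
                          structure, mode, covariates)
  pv <- panel_intervals(data, sspace, covariates)
  # warn when a modelled transition never appears in the data
  obs <- unique(paste(pv$from, pv$to))
  mod <- paste(structure_index(structure)[, 1], structure_index(structure)[, 2])
  if (!all(mod %in% obs))
    warn(paste0("no observed transitions for: ",
                paste(transition_names(structure)[!(mod %in% obs)], collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)
  ka <- kernel_args(template)
  best <- NULL
  n_bad <- 0L
  for (r in seq_len(control$restarts)) {
    theta0 <- if (!is.null(init)) {
      if (length(init) != n_parameters(template)) abort("`init` has the wrong length")
      as.numeric(init)
    } else if (control$init_policy == "user") {
      abort("init_policy 'user' requires `init`")
    } else {
      init_parameters(control$init_policy, template, data = data, control = control)
    }
    run <- run_sgd(pv, template, theta0, control)
    if (!all(is.finite(run$theta))) { n_bad <- n_bad + 1L; next }
    pieces <- theta_pieces(run$theta, template, control$scale)
    ll <- cpp_panel_loglik(ka$S, ka$allowed, pieces$q0, pieces$beta, ka$indep,
                           FALSE, pv$from, pv$to, pv$tau, pv$Z,
                           seq_len(pv$n) - 1L)$loglik
    if (is.null(best) || ll > best$loglik) {
      best <- list(theta = run$theta, loglik = ll, run = run, restart = r,
                   theta0 = theta0)
    }
  }
  if (is.null(best))
    abort(sprintf("all %d restarts diverged (%d non-finite)", control$restarts, n_bad))
  theta_hat <- as.numeric(best$theta)
  names(theta_hat) <- names(params_to_theta(template, scale = control$scale))
  params_hat <- theta_to_params(theta_hat, template, scale = control$scale)
  structure(
    list(theta_hat = theta_hat, params_hat = params_hat,
         loglik = best$loglik, converged = best$run$converged,
         n_iters = best$run$n_iters, restart_index = best$restart,
         trace = best$run$trace, control = control, scale = control$scale,
         template = template, M = pv$M, n_intervals = pv$n,
         covariates = covariates, seed = seed,
         centering = attr(data, "centering"),
         n_failed_restarts = n_bad),
    class = "ctmm_fit"
  )
}

#' @export
print.ctmm_fit <- function(x, ...) {
  cat("<ctmm_fit> ", x$params_hat$mode, " | M = ", x$M,
      " subjects, ", x$n_intervals, " intervals\n",
      "log-likelihood: ", format(x$loglik, digits = 8),
      "  (restart ", x$restart_index, ", ",
      x$n_iters, " iters, converged: ", x$converged, ")\n", sep = "")
  print(round(x$params_hat$q0, 4))
  invisible(x)
}
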