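# Monte-Carlo operating characteristics (bias, variance, coverage,
# rejection rate) and descriptive panel summaries.

#' Define a Monte-Carlo scenario
#'
#' A scenario fixes the data-generating truth and the fitting/inference
#' settings for [run_scenario()].  The default truth uses a
#' distance-decay baseline pattern `q0_ij = q0_base / |i - j|` over the
#' given transition structure and one common coefficient value
#' `true_beta` for every live coefficient (0 gives the null scenario).
#'
#' @param M Subjects per replicate.
#' @param S Number of states (labels `1..S`).
#' @param R Number of covariates.
#' @param true_beta Common true value of all coefficients.
#' @param q0_base Numerator of the distance-decay baseline pattern.
#' @param structure Transition structure; default: adjacent (birth-death)
#'   transitions, the dominant moves of an ordinal disability scale.
#' @param n_replicates Monte-Carlo replicates.
#' @param ci_method Hessian construction for the intervals.
#' @param t_max,dummy_interval Follow-up and scheduled-visit spacing of
#'   the simulator (every 6 months by default, giving roughly 30
#'   observations per subject over 15 time units).
#' @param control [ctmm_control()] used for each replicate's fit.
#' @param seed Scenario seed; replicate seeds are derived from it.
#' @export
mc_scenario <- function(M = 500, S = 8, R = 10, true_beta = 0, q0_base = 0.5,
                        structure = NULL, n_replicates = 100,
                        ci_method = c("pade", "power_series"),
                        t_max = 15, dummy_interval = 0.5,
                        control = ctmm_control(restarts = 2, max_iters = 300,
                                               batch_size = 100),
                        seed = 1) {
  ci_method <- match.arg(ci_method)
  ss <- state_space(seq_len(S))
  structure <- structure %||% all_transitions(ss, max_jump = 1)
  idx <- structure_index(structure)
  q0 <- q0_base / pmax(abs(idx[, 1] - idx[, 2]), 1)
  covn <- if (R > 0) paste0("z", seq_len(R)) else character()
  beta <- if (R > 0) matrix(true_beta, nrow(structure), R) else NULL
  truth <- ctmm_params(q0, beta, structure, covariate_names = covn)
  structure(list(M = M, S = S, R = R, true_beta = true_beta,
                 q0_base = q0_base, truth = truth,
                 n_replicates = n_replicates, ci_method = ci_method,
                 t_max = t_max, dummy_interval = dummy_interval,
                 control = control, seed = seed),
            class = "mc_scenario")
}

#' Run a Monte-Carlo scenario
#'
#' For each replicate: simulate a panel from the scenario truth, fit the
#' model, build Wald intervals, and score the estimates against the
#' truth.  Failed fits are counted and excluded with a warning.
#'
#' @param spec An [mc_scenario()].
#' @param progress Print a dot per replicate.
#' @return A list of class `ctmm_mc`: `per_parameter` (bias, variance,
#'   coverage, rejection per parameter), `aggregate` (means per
#'   parameter class; bias aggregated as the mean absolute
#'   per-parameter bias so signs cannot cancel), `n_failed`,
#'   `mean_n_obs` (realized observation count).
#' @export
run_scenario <- function(spec, progress = FALSE) {
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_replicates)
  truth <- spec$truth
  theta_true <- params_to_theta(truth, scale = "raw")
  cfg <- sim_config(spec$M, truth, t_max = spec$t_max,
                    dummy_interval = spec$dummy_interval)
  rows <- list()
  n_failed <- 0L
  n_obs <- numeric(0)
  for (r in seq_len(spec$n_replicates)) {
    res <- tryCatch({
      dat <- simulate_panel(cfg, seed = rep_seeds[r])
      fit <- ctmm_fit(dat, truth$structure, mode = truth$mode,
                      covariates = truth$covariate_names,
                      control = spec$control, seed = rep_seeds[r] %% 100000L + 1L)
      ci <- ctmm_ci(dat, fit, method = spec$ci_method)
      list(ci = ci, n = nrow(dat))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    ci <- res$ci
    ci$replicate <- r
    ci$truth <- unname(theta_true)
    rows[[length(rows) + 1L]] <- ci
    n_obs <- c(n_obs, res$n)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  if (length(rows) == 0) abort("every replicate failed")
  if (n_failed > 0)
    warn(sprintf("%d of %d replicates failed and were excluded",
                 n_failed, spec$n_replicates))
  all <- dplyr::bind_rows(rows)
  per <- all |>
    dplyr::group_by(.data$term, .data$type, .data$transition, .data$covariate) |>
    dplyr::summarise(
      truth = .data$truth[1],
      bias = mean(.data$estimate - .data$truth),
      variance = stats::var(.data$estimate),
      coverage = mean(.data$conf.low <= .data$truth & .data$truth <= .data$conf.high),
      rejection = mean(.data$reject),
      .groups = "drop")
  agg <- per |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(bias = mean(abs(.data$bias)),
                     variance = mean(.data$variance),
                     coverage = mean(.data$coverage),
                     rejection = mean(.data$rejection), .groups = "drop")
  structure(list(per_parameter = per, aggregate = agg,
                 estimates = all, n_failed = n_failed,
                 n_replicates = spec$n_replicates,
                 mean_n_obs = mean(n_obs), spec = spec),
            class = "ctmm_mc")
}

#' @export
print.ctmm_mc <- function(x, ...) {
  cat("<ctmm_mc>", x$n_replicates - x$n_failed, "successful replicates",
      sprintf("(mean N = %.0f observations)\n", x$mean_n_obs))
  print(as.data.frame(x$aggregate), digits = 3)
  invisible(x)
}

#' Normalized empirical transition matrix
#'
#' Counts of adjacent-observation (from, to) state pairs, each row
#' normalized to sum to one.  Rows never observed as a starting state
#' are all-zero and flagged in the `empty_rows` attribute.
#'
#' @param data Panel data.
#' @param state_space A [state_space()]; inferred from the observed
#'   states when omitted.
#' @return `S x S` row-stochastic matrix.
#' @export
empirical_transition_matrix <- function(data, state_space = NULL) {
  state_space <- state_space %||% state_space(sort(unique(data$state)))
  pv <- panel_intervals(data, state_space, covariates = character())
  S <- state_space$S
  counts <- matrix(0, S, S, dimnames = list(state_space$labels,
                                            state_space$labels))
  for (n in seq_along(pv$from))
    counts[pv$from[n] + 1L, pv$to[n] + 1L] <- counts[pv$from[n] + 1L, pv$to[n] + 1L] + 1
  tot <- rowSums(counts)
  P <- counts / ifelse(tot == 0, 1, tot)
  attr(P, "empty_rows") <- state_space$labels[tot == 0]
  P
}

#' Filter transitions by observed frequency
#'
#' Keeps the ordered pairs whose adjacent-observation count is at least
#' `threshold` of all observed off-diagonal transitions (boundary
#' inclusive), dropping rarely observed transitions from the model the
#' way sparse panels are usually pruned before fitting covariate
#' effects.
#'
#' @param data Panel data.
#' @param threshold Fraction in `[0, 1)` of total off-diagonal
#'   transition count (default 0.01, i.e. 1%).
#' @param state_space Optional [state_space()].
#' @return A [transition_structure()] of the retained pairs.
#' @export
transition_frequency_filter <- function(data, threshold = 0.01,
                                        state_space = NULL) {
  if (threshold < 0 || threshold >= 1) abort("`threshold` must be in [0, 1)")
  state_space <- state_space %||% state_space(sort(unique(data$state)))
  pv <- panel_intervals(data, state_space, covariates = character())
  off <- pv$from != pv$to
  if (!any(off)) abort("no off-diagonal transitions observed: model would be vacuous")
  key <- paste(pv$from[off], pv$to[off])
  tab <- table(key)
  keep <- tab / sum(tab) >= threshold
  if (!any(keep)) abort("threshold removed every transition: model would be vacuous")
  pairs <- do.call(rbind, strsplit(names(tab)[keep], " "))
  fi <- as.integer(pairs[, 1]); ti <- as.integer(pairs[, 2])
  ord <- order(fi, ti)
  transition_structure(state_space$labels[fi[ord] + 1L],
                       state_space$labels[ti[ord] + 1L], state_space)
}

#' Collapse raw EDSS scores to modelling states
#'
#' The Expanded Disability Status Scale takes half-point values in
#' 0..10; for state-space modelling 0 stays 0, values are otherwise
#' rounded down to their integer part, and everything at or above 8 is
#' merged into state 8, giving 9 states.
#'
#' @param x Numeric EDSS values in `[0, 10]`.
#' @return Integer state labels in `0..8`.
#' @examples
#' collapse_edss(c(0, 1.5, 2.5, 7.5, 9.5))
#' @export
collapse_edss <- function(x) {
  if (any(x < 0 | x > 10, na.rm = TRUE)) abort("EDSS values must lie in [0, 10]")
  as.integer(pmin(floor(x), 8))
}
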