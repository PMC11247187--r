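# Panel CSV and fit serialization.
#
# Long-format CSV dialect: comma-separated, UTF-8, mandatory header,
# '.' decimal.  Required columns subject_id, time, state; every other
# numeric column is treated as a covariate unless declared.  Time units
# are whatever the file uses (years recommended); rates are "per time
# unit of the input".

#' Read a long-format panel CSV
#'
#' Validates and sorts the panel: rows are ordered by (subject, time),
#' times must be strictly increasing within subject, duplicate
#' (subject, time) rows and unknown state labels are errors, and
#' covariates must be complete (no imputation is attempted).
#'
#' @param path CSV file path.
#' @param covariates Covariate columns; default: all remaining numeric
#'   columns.
#' @param state_space Optional [state_space()] restricting the legal
#'   state labels.
#' @param center Center the covariates at their mean? The offsets are
#'   stored in the `centering` attribute so hazard ratios can be
#'   reported at interpretable covariate values.
#' @param collapse_states Apply [collapse_edss()] to the state column
#'   (for raw EDSS input).
#' @return A validated panel tibble.
#' @export
read_panel <- function(path, covariates = NULL, state_space = NULL,
                       center = FALSE, collapse_states = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("subject_id", "time", "state"))
    if (!col %in% names(data)) abort(paste0("missing required column `", col, "`"))
  if (collapse_states) data$state <- collapse_edss(data$state)
  dup <- duplicated(data[c("subject_id", "time")])
  if (any(dup)) {
    off <- unique(data$subject_id[dup])
    abort(paste0("duplicate (subject, time) rows for: ",
                 paste(utils::head(off, 5), collapse = ", ")))
  }
  data <- dplyr::arrange(data, match(.data$subject_id, unique(data$subject_id)),
                         .data$time)
  covariates <- covariates %||% covariate_columns(data)
  if (length(covariates) > 0 && anyNA(data[covariates]))
    abort("covariates contain missing values")
  sspace <- state_space %||% state_space(sort(unique(data$state)))
  state_index(sspace, data$state)  # errors on unknown labels
  # triggers the strictly-increasing-times check
  panel_intervals(data, sspace, covariates)
  if (center && length(covariates) > 0) {
    offsets <- vapply(data[covariates], mean, numeric(1))
    for (v in covariates) data[[v]] <- data[[v]] - offsets[[v]]
    attr(data, "centering") <- offsets
  }
  attr(data, "covariates") <- covariates
  data
}

#' Write a panel to CSV
#'
#' Canonical column order: `subject_id`, `time`, `state`, covariates.
#'
#' @param data Panel tibble.
#' @param path Output path.
#' @export
write_panel <- function(data, path) {
  covariates <- covariate_columns(data)
  readr::write_csv(data[c("subject_id", "time", "state", covariates)], path,
                   progress = FALSE)
  invisible(path)
}

config_hash <- function(control) {
  # a cheap stable fingerprint of the fit configuration
  s <- paste(deparse(control[order(names(control))]), collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 1e9
}

#' Serialize a fit to JSON
#'
#' Stores the estimate on both scales, the model description, the
#' log-likelihood, seed and a configuration fingerprint; the file
#' round-trips through [read_fit()].
#'
#' @param fit A `ctmm_fit`.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  p <- fit$params_hat
  obj <- list(
    package_version = as.character(utils::packageVersion("sctmm")),
    state_labels = p$state_space$labels,
    from = p$structure$from, to = p$structure$to,
    mode = p$mode, covariates = p$covariate_names,
    q0 = unname(p$q0), beta = p$beta,
    theta_scale = fit$scale, theta_hat = unname(fit$theta_hat),
    loglik = fit$loglik, converged = fit$converged,
    n_iters = fit$n_iters, restart_index = fit$restart_index,
    M = fit$M, n_intervals = fit$n_intervals, seed = fit$seed,
    centering = as.list(fit$centering %||% stats::setNames(numeric(), character())),
    config_hash = config_hash(fit$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a serialized fit
#'
#' @param path JSON file written by [write_fit()].
#' @param control Optional [ctmm_control()]; a fingerprint mismatch
#'   against the stored configuration raises a warning.
#' @return A list of class `ctmm_fit_loaded` with the estimated
#'   parameters ([ctmm_params()]), theta, log-likelihood and metadata.
#' @export
read_fit <- function(path, control = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(control) && config_hash(control) != obj$config_hash)
    warn("fit was produced under a different configuration")
  ss <- state_space(obj$state_labels)
  st <- transition_structure(obj$from, obj$to, ss)
  beta <- if (length(obj$covariates) > 0) as.matrix(obj$beta) else NULL
  params <- ctmm_params(obj$q0, beta, st, obj$mode,
                        covariate_names = as.character(obj$covariates %||% character()))
  theta <- obj$theta_hat
  names(theta) <- names(params_to_theta(params, scale = obj$theta_scale))
  structure(list(params_hat = params, theta_hat = theta, scale = obj$theta_scale,
                 loglik = obj$loglik, converged = obj$converged,
                 n_iters = obj$n_iters, restart_index = obj$restart_index,
                 M = obj$M, n_intervals = obj$n_intervals, seed = obj$seed,
                 centering = unlist(obj$centering),
                 config_hash = obj$config_hash,
                 template = params),
            class = c("ctmm_fit_loaded", "ctmm_fit"))
}
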