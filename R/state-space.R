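# State space and transition structure containers.
#
# External state labels (e.g. EDSS 0..8) are decoupled from the 0-based
# contiguous indices used by the linear algebra; the mapping happens at
# the package boundary, never inside the numeric kernels.

#' Define a finite state space
#'
#' @param labels Ordered vector of unique external state labels (numeric
#'   or character), e.g. `0:8` for collapsed EDSS states.
#' @return An object of class `ctmm_state_space` holding the labels, the
#'   number of states `S`, and the label-to-index mapping.
#' @examples
#' state_space(0:3)
#' @export
state_space <- function(labels) {
  if (anyDuplicated(labels)) abort("state labels must be unique")
  if (length(labels) < 2) abort("a state space needs at least 2 states")
  structure(
    list(labels = labels, S = length(labels),
         index_map = stats::setNames(seq_along(labels) - 1L, as.character(labels))),
    class = "ctmm_state_space"
  )
}

#' @export
print.ctmm_state_space <- function(x, ...) {
  cat("<ctmm_state_space> S =", x$S, ":", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

state_index <- function(sspace, labels) {
  idx <- sspace$index_map[as.character(labels)]
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    abort(paste0("unknown state label(s): ", paste(bad, collapse = ", ")))
  }
  unname(idx)
}

#' Declare the set of modelled transitions
#'
#' Off-diagonal intensities not listed here are structurally zero and
#' carry no parameters.
#'
#' @param from,to Equal-length vectors of external state labels for the
#'   ordered pairs (i, j), i != j, whose intensity is modelled.
#' @param state_space A [state_space()] object.
#' @return A tibble of class `ctmm_structure` with columns `from`, `to`.
#' @examples
#' ss <- state_space(0:2)
#' transition_structure(c(0, 1, 1, 2), c(1, 0, 2, 1), ss)
#' @export
transition_structure <- function(from, to, state_space) {
  if (length(from) != length(to)) abort("`from` and `to` must have equal length")
  if (length(from) < 1) abort("at least one transition must be allowed")
  fi <- state_index(state_space, from)
  ti <- state_index(state_space, to)
  if (any(fi == ti)) abort("diagonal pairs (i, i) are not transitions")
  key <- paste(fi, ti)
  if (anyDuplicated(key)) abort("duplicated transition pairs")
  out <- tibble::tibble(from = from, to = to)
  attr(out, "state_space") <- state_space
  class(out) <- c("ctmm_structure", class(out))
  out
}

#' All pairwise transitions of a state space
#'
#' @param state_space A [state_space()] object.
#' @param max_jump Optional cap on `|i - j|` measured in index distance;
#'   `1` gives a birth-death (adjacent-only) structure.
#' @return A `ctmm_structure`.
#' @export
all_transitions <- function(state_space, max_jump = Inf) {
  S <- state_space$S
  grid <- expand.grid(i = seq_len(S), j = seq_len(S))
  grid <- grid[grid$i != grid$j & abs(grid$i - grid$j) <= max_jump, ]
  grid <- grid[order(grid$i, grid$j), ]
  transition_structure(state_space$labels[grid$i], state_space$labels[grid$j],
                       state_space)
}

# internal 0-based K x 2 matrix of a structure
structure_index <- function(struct) {
  ss <- attr(struct, "state_space")
  cbind(state_index(ss, struct$from), state_index(ss, struct$to))
}

transition_names <- function(struct) paste0(struct$from, "->", struct$to)
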