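#' Construct a transition-count object
#'
#' Low-level constructor for a 3x3 matrix of observed transition counts
#' `n[i, j]` = number of ordered adjacent fixation pairs moving from state
#' `i` to state `j`, pooled over all sequences of one group.
#'
#' @param n 3x3 matrix of nonnegative integer counts (rows = origin state).
#' @param group Optional group label.
#' @return An object of class `transition_counts`.
#' @seealso [count_transitions()] to tally counts from sequences.
#' @export
transition_counts <- function(n, group = NULL) {
  n <- as.matrix(n)
  if (nrow(n) != n_states() || ncol(n) != n_states()) {
    stop("n must be a ", n_states(), "x", n_states(), " matrix", call. = FALSE)
  }
  if (any(n < 0) || any(n != round(n))) {
    stop("transition counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(n) <- "double"
  dimnames(n) <- list(aoi_states(), aoi_states())
  structure(
    list(n = n, states = aoi_states(), group = group, n_total = sum(n)),
    class = "transition_counts"
  )
}

#' Tally transition counts from state sequences
#'
#' Counts ordered adjacent state pairs within each (participant, display)
#' block and pools them. Transitions never bridge two displays, and
#' consecutive same-state fixations count as self-transitions. The total
#' count equals the summed sequence lengths minus the number of blocks.
#'
#' @param sequences Sequence tibble from [build_sequences()] (columns
#'   `participant_id`, `group`, `display_id`, `position`, `state`).
#' @param group Optional group label: sequences are restricted to that
#'   group. When `NULL` all rows are pooled, which requires a single group
#'   label in the data.
#' @return A [transition_counts()] object.
#' @export
#' @examples
#' seqs <- state_sequence(c("FACE", "OBJECT", "OBJECT", "NO_STIMULUS"))
#' count_transitions(seqs)$n
count_transitions <- function(sequences, group = NULL) {
  if (!is.null(group)) {
    sequences <- dplyr::filter(sequences, .data$group == !!group)
  } else {
    labs <- unique(as.character(sequences$group))
    if (length(labs) > 1) {
      stop("sequences contain several groups (",
           paste(labs, collapse = ", "),
           "); supply `group` to select one", call. = FALSE)
    }
    group <- if (length(labs) == 1) labs else NULL
  }
  pairs <- sequences |>
    dplyr::arrange(.data$participant_id, .data$display_id, .data$position) |>
    dplyr::group_by(.data$participant_id, .data$display_id) |>
    dplyr::mutate(to = dplyr::lead(.data$state)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to))
  if (nrow(pairs) == 0) {
    stop("no transitions observed", call. = FALSE)
  }
  n <- table(from = as_aoi_factor(pairs$state), to = as_aoi_factor(pairs$to))
  transition_counts(unclass(n), group = group)
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"),
      ": ", format(x$n_total, big.mark = ","), " transitions\n", sep = "")
  print(x$n)
  invisible(x)
}

as_transition_counts <- function(x, arg = "counts") {
  if (inherits(x, "transition_counts")) return(x)
  if (is.matrix(x)) return(transition_counts(x))
  stop(arg, " must be a transition_counts object or a 3x3 count matrix",
       call. = FALSE)
}
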