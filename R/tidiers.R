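#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transition-count object
#'
#' @param x A [transition_counts()] object.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `n`.
#' @export
#' @exportS3Method generics::tidy
tidy.transition_counts <- function(x, ...) {
  tidyr::expand_grid(from = x$states, to = x$states) |>
    dplyr::mutate(n = as.vector(t(x$n)))
}

#' Tidy a fitted transition matrix
#'
#' One row per cell with the point estimate, standard error and confidence
#' interval, in broom's `estimate` / `conf.low` / `conf.high` vocabulary.
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
#' @exportS3Method generics::tidy
tidy.transition_fit <- function(x, ...) {
  flat <- function(m) as.vector(t(m))
  tidyr::expand_grid(from = x$states, to = x$states) |>
    dplyr::mutate(
      estimate = flat(x$p_hat),
      std.error = flat(x$se),
      conf.low = flat(x$ci_low),
      conf.high = flat(x$ci_high)
    )
}

#' One-line summary of a fitted transition matrix
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_transitions`, `n_states`, `level`,
#'   `se_mode`, `group`.
#' @export
#' @exportS3Method generics::glance
glance.transition_fit <- function(x, ...) {
  tibble::tibble(
    n_transitions = if (is.null(x$row_totals)) NA_real_ else
      sum(x$row_totals),
    n_states = length(x$states),
    level = x$level,
    se_mode = x$se_mode,
    group = x$group %||% NA_character_
  )
}

#' Tidy a steady-state distribution
#'
#' @param x A `steady_state` object.
#' @param ... Unused.
#' @return A tibble with columns `state`, `estimate` and, when bootstrap
#'   intervals are present, `conf.low` / `conf.high`.
#' @export
#' @exportS3Method generics::tidy
tidy.steady_state <- function(x, ...) {
  out <- tibble::tibble(
    state = factor(x$states, levels = x$states),
    estimate = unname(x$pi)
  )
  if (!is.null(x$ci_low)) {
    out$conf.low <- unname(x$ci_low)
    out$conf.high <- unname(x$ci_high)
  }
  out
}

#' Tidy a chain test result
#'
#' @param x A `chain_test` (from [verify_markov_property()] or
#'   [divergence_test()]).
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`,
#'   `convention`.
#' @export
#' @exportS3Method generics::tidy
tidy.chain_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$statistic),
    df = unname(x$parameter),
    p.value = x$p.value,
    method = x$method,
    convention = x$convention
  )
}

#' @rdname tidy.chain_test
#' @export
#' @exportS3Method generics::glance
glance.chain_test <- function(x, ...) tidy.chain_test(x, ...)
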