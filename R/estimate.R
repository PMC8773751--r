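#' Maximum-likelihood estimate of a gaze transition matrix
#'
#' Estimates the first-order transition matrix from pooled counts by the
#' relative-frequency MLE `p_hat[i, j] = n[i, j] / sum_u n[i, u]`, with
#' per-cell standard errors and normal-approximation confidence intervals
#' truncated to `[0, 1]`.
#'
#' Two standard-error conventions are available. `"paper"` (the default)
#' uses `se[i, j] = p_hat[i, j] / sqrt(n[i, j])`, the form quoted alongside
#' the MLE in the applied eye-tracking literature this package follows;
#' cells with `n[i, j] = 0` get `se = 0` and a degenerate `[0, 0]` interval.
#' `"binomial"` uses the familiar row-multinomial form
#' `sqrt(p_hat (1 - p_hat) / row_total)`. Both are exposed because published
#' tables do not always say which was used.
#'
#' @param counts A [transition_counts()] object or a 3x3 count matrix.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param se_mode `"paper"` or `"binomial"` (see Details).
#' @return An object of class `transition_fit` with matrices `p_hat`, `se`,
#'   `ci_low`, `ci_high`, the `row_totals`, `level`, `se_mode` and the
#'   originating counts. Every row of `p_hat` sums to 1.
#' @seealso [steady_state()], [departure_probabilities()],
#'   [cell_difference_flags()], [tidy.transition_fit()]
#' @export
#' @examples
#' cts <- transition_counts(matrix(c(2, 1, 1, 0, 4, 0, 1, 1, 2), 3,
#'                                 byrow = TRUE))
#' fit <- estimate_transition_matrix(cts)
#' fit$p_hat
estimate_transition_matrix <- function(counts, level = 0.95,
                                       se_mode = c("paper", "binomial")) {
  counts <- as_transition_counts(counts)
  se_mode <- match.arg(se_mode)
  stopifnot(is.numeric(level), length(level) == 1, level > 0, level < 1)

  n <- counts$n
  row_totals <- rowSums(n)
  if (any(row_totals == 0)) {
    never <- counts$states[row_totals == 0]
    stop("state(s) never observed as an origin: ",
         paste(never, collapse = ", "), call. = FALSE)
  }
  p_hat <- n / row_totals
  se <- switch(se_mode,
    paper = {
      s <- matrix(0, n_states(), n_states(), dimnames = dimnames(n))
      pos <- n > 0
      s[pos] <- p_hat[pos] / sqrt(n[pos])
      s
    },
    binomial = sqrt(p_hat * (1 - p_hat) / row_totals)
  )
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_low <- pmax(p_hat - z * se, 0)
  ci_high <- pmin(p_hat + z * se, 1)

  new_transition_fit(p_hat = p_hat, se = se, ci_low = ci_low,
                     ci_high = ci_high, level = level, se_mode = se_mode,
                     row_totals = row_totals, group = counts$group,
                     counts = n)
}

new_transition_fit <- function(p_hat, se, ci_low, ci_high, level, se_mode,
                               row_totals = NULL, group = NULL,
                               counts = NULL) {
  structure(
    list(p_hat = p_hat, se = se, ci_low = ci_low, ci_high = ci_high,
         level = level, se_mode = se_mode, row_totals = row_totals,
         group = group, counts = counts, states = aoi_states()),
    class = "transition_fit"
  )
}

#' Assemble a transition_fit from externally reported values
#'
#' Builds a `transition_fit` directly from a point-estimate matrix and
#' (optionally) its interval endpoints — useful for comparing against
#' published transition tables for which raw counts are unavailable, e.g.
#' with [cell_difference_flags()].
#'
#' @param p_hat 3x3 row-stochastic matrix of point estimates.
#' @param ci_low,ci_high Optional 3x3 matrices of interval endpoints.
#' @param level Confidence level the intervals refer to.
#' @param group Optional group label.
#' @return A `transition_fit` object (with `se = NA` where unknown).
#' @export
transition_fit <- function(p_hat, ci_low = NULL, ci_high = NULL,
                           level = 0.95, group = NULL) {
  p_hat <- check_stochastic(p_hat, tol = 0.015, arg = "p_hat")
  shape <- function(m, arg) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    stopifnot(nrow(m) == n_states(), ncol(m) == n_states())
    dimnames(m) <- dimnames(p_hat)
    m
  }
  ci_low <- shape(ci_low, "ci_low")
  ci_high <- shape(ci_high, "ci_high")
  if (!is.null(ci_low) && !is.null(ci_high) &&
      (any(ci_low > p_hat + 1e-9) || any(ci_high < p_hat - 1e-9))) {
    stop("intervals must bracket p_hat", call. = FALSE)
  }
  na <- matrix(NA_real_, n_states(), n_states(), dimnames = dimnames(p_hat))
  new_transition_fit(p_hat = p_hat, se = na,
                     ci_low = ci_low %||% na, ci_high = ci_high %||% na,
                     level = level, se_mode = "external", group = group)
}

#' @export
print.transition_fit <- function(x, digits = 2, ...) {
  cat("Gaze transition matrix",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  cat(sprintf("%d%% CI, se mode: %s\n", round(100 * x$level), x$se_mode))
  cell <- matrix(
    sprintf("%.*f [%.*f-%.*f]", digits, x$p_hat, digits, x$ci_low,
            digits, x$ci_high),
    n_states(), dimnames = dimnames(x$p_hat)
  )
  print(cell, quote = FALSE)
  invisible(x)
}

#' Per-state departure probabilities
#'
#' The probability of leaving each AOI state on the next fixation,
#' `1 - p_hat[i, i]` — the quantity contrasted between groups when asking
#' how "sticky" each gaze state is.
#'
#' @param fit A `transition_fit`.
#' @return A tibble with columns `state`, `p_stay`, `p_depart` (and the
#'   group label if the fit carries one).
#' @export
#' @examples
#' cts <- transition_counts(diag(3) * 5 + 1)
#' departure_probabilities(estimate_transition_matrix(cts))
departure_probabilities <- function(fit) {
  stopifnot(inherits(fit, "transition_fit"))
  out <- tibble::tibble(
    state = factor(fit$states, levels = fit$states),
    p_stay = unname(diag(fit$p_hat)),
    p_depart = unname(1 - diag(fit$p_hat))
  )
  if (!is.null(fit$group)) out <- dplyr::mutate(out, group = fit$group,
                                                .before = 1)
  out
}

#' Transition-graph edge list
#'
#' Exports the estimated chain as a (from, to, probability) edge tibble for
#' graph tools or plotting — the tabular analogue of the usual
#' directed-graph rendering of a gaze transition matrix.
#'
#' @param fit A `transition_fit`.
#' @param min_probability Edges below this probability are dropped.
#' @return A tibble with columns `from`, `to`, `probability`.
#' @export
transition_edges <- function(fit, min_probability = 0) {
  stopifnot(inherits(fit, "transition_fit"))
  edges <- tidyr::expand_grid(from = fit$states, to = fit$states) |>
    dplyr::mutate(probability = as.vector(t(fit$p_hat)))
  dplyr::filter(edges, .data$probability >= min_probability)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
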