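#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a fitted transition matrix
#'
#' Tile plot of the estimated transition probabilities, each cell labelled
#' with its point estimate and confidence interval — a graphical analogue
#' of a published transition table.
#'
#' @param object A `transition_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.transition_fit <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      from = factor(.data$from, levels = rev(aoi_states())),
      to = factor(.data$to, levels = aoi_states()),
      label = ifelse(is.na(.data$conf.low),
                     sprintf("%.2f", .data$estimate),
                     sprintf("%.2f\n[%.2f, %.2f]", .data$estimate,
                             .data$conf.low, .data$conf.high))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "P(to | from)") +
    ggplot2::labs(
      x = "Next fixation (to)", y = "Current fixation (from)",
      title = paste0("Gaze transition probabilities",
                     if (!is.null(object$group))
                       paste0(" - ", object$group))
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a steady-state distribution
#'
#' @param object A `steady_state` (bootstrap intervals drawn when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.steady_state <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$state,
                                       y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "Long-run occupancy",
      title = paste0("Steady-state distribution",
                     if (!is.null(object$group))
                       paste0(" - ", object$group))
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("conf.low" %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15
    )
  }
  p
}

#' Compare departure probabilities between two groups
#'
#' Side-by-side bars of `1 - p[i, i]` per AOI state for two fitted chains:
#' how likely each group is to move away from its current gaze state on
#' the next fixation.
#'
#' @param fit_a,fit_b `transition_fit` objects for the two groups.
#' @param labels Length-2 character vector of group labels (defaults to
#'   the fits' own labels, else "A"/"B").
#' @return A ggplot object.
#' @export
plot_departure_comparison <- function(fit_a, fit_b, labels = NULL) {
  labels <- labels %||% c(fit_a$group %||% "A", fit_b$group %||% "B")
  d <- dplyr::bind_rows(
    dplyr::mutate(departure_probabilities(fit_a), group = labels[1]),
    dplyr::mutate(departure_probabilities(fit_b), group = labels[2])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$p_depart,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge", width = 0.7) +
    ggplot2::labs(x = NULL, y = "P(departure on next fixation)",
                  fill = NULL,
                  title = "Departure probability by AOI state") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
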