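#' Test the Markov (first-order) property of fixation sequences
#'
#' Likelihood-ratio test of first-order against second-order dependence.
#' Triples of consecutive states are pooled within (participant, display)
#' blocks — never across display boundaries — and the statistic is
#' `G2 = 2 * sum_ijk n_ijk * log(p(k | i, j) / p(k | j))`, with
#' `p(k | i, j) = n_ijk / n_ij.` and `p(k | j) = n_.jk / n_.j.`; terms with
#' `n_ijk = 0` contribute 0. A small p-value rejects the first-order model.
#'
#' Two degrees-of-freedom conventions are offered for the chi-square
#' reference: `"standard"` uses the likelihood-ratio counting
#' `m * (m - 1)^2` (= 12 for three states); `"paper_compatible"`, the
#' default, uses `m^3` (= 27), the convention printed by the `markovchain`
#' package's order test and common in applied reports. The statistic is
#' identical under both; only the reference df (hence p-value) changes.
#'
#' @param sequences Sequence tibble from [build_sequences()].
#' @param convention `"paper_compatible"` or `"standard"` (see Details).
#' @return A `chain_test` object (also of class `htest`): statistic, df,
#'   p-value, convention.
#' @export
verify_markov_property <- function(sequences,
                                   convention = c("paper_compatible",
                                                  "standard")) {
  convention <- match.arg(convention)
  m <- n_states()
  triples <- sequences |>
    dplyr::arrange(.data$participant_id, .data$display_id, .data$position) |>
    dplyr::group_by(.data$participant_id, .data$display_id) |>
    dplyr::mutate(s1 = dplyr::lead(.data$state),
                  s2 = dplyr::lead(.data$state, 2)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$s2))
  if (nrow(triples) == 0) {
    stop("sequences too short for order test (no state triples)",
         call. = FALSE)
  }
  n_ijk <- table(i = as_aoi_factor(triples$state),
                 j = as_aoi_factor(triples$s1),
                 k = as_aoi_factor(triples$s2))
  n_ijk <- array(as.numeric(n_ijk), dim = c(m, m, m))
  n_ij <- apply(n_ijk, c(1, 2), sum)          # n_ij.
  n_jk <- apply(n_ijk, c(2, 3), sum)          # n_.jk
  n_j <- rowSums(n_jk)                        # n_.j.

  g2 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(m)) {
    nijk <- n_ijk[i, j, k]
    if (nijk > 0) {
      p2 <- nijk / n_ij[i, j]
      p1 <- n_jk[j, k] / n_j[j]
      g2 <- g2 + 2 * nijk * log(p2 / p1)
    }
  }
  g2 <- max(g2, 0)
  df <- switch(convention, standard = m * (m - 1)^2, paper_compatible = m^3)
  new_chain_test(statistic = g2, df = df,
                 method = "Markov property (first- vs second-order) G-test",
                 convention = convention,
                 data.name = deparse(substitute(sequences)))
}

#' Divergence (homogeneity) test between two groups' chains
#'
#' Kullback-style likelihood-ratio test of whether two empirically
#' estimated transition matrices arise from the same underlying chain. With
#' pooled estimate `p0` from the summed counts, the statistic is
#' `2 * sum_g sum_ij n_ij^g * log(p_ij^g / p0_ij)` (zero-count terms
#' contribute 0), referred to a chi-square upper tail.
#'
#' Degrees of freedom: `"paper_compatible"` (default) uses
#' `(G - 1) * (m^2 - 1)` = 8 for two groups of three states, matching the
#' convention of applied reports built on the `markovchain` package;
#' `"standard"` uses the likelihood-ratio counting `(G - 1) * m * (m - 1)`
#' = 6.
#'
#' @param counts_a,counts_b [transition_counts()] for the two groups (or
#'   3x3 count matrices). Both must have every state observed as an origin,
#'   and distinct group labels if labels are carried.
#' @param convention `"paper_compatible"` or `"standard"`.
#' @return A `chain_test` object: statistic, df, p-value, convention.
#' @export
#' @examples
#' a <- transition_counts(matrix(c(40, 40, 20, 20, 60, 20, 25, 50, 25),
#'                               3, byrow = TRUE), group = "TD")
#' divergence_test(a, a)$p.value   # identical chains -> 1
divergence_test <- function(counts_a, counts_b,
                            convention = c("paper_compatible", "standard")) {
  convention <- match.arg(convention)
  counts_a <- as_transition_counts(counts_a, "counts_a")
  counts_b <- as_transition_counts(counts_b, "counts_b")
  if (!is.null(counts_a$group) && !is.null(counts_b$group) &&
      identical(counts_a$group, counts_b$group)) {
    stop("the two count sets carry the same group label (",
         counts_a$group, ")", call. = FALSE)
  }
  m <- n_states()
  for (cts in list(counts_a, counts_b)) {
    rt <- rowSums(cts$n)
    if (any(rt == 0)) {
      stop("state(s) never observed as an origin in group ",
           cts$group %||% "(unlabelled)", ": ",
           paste(aoi_states()[rt == 0], collapse = ", "), call. = FALSE)
    }
  }
  pooled <- counts_a$n + counts_b$n
  p0 <- pooled / rowSums(pooled)
  stat <- 0
  for (n_g in list(counts_a$n, counts_b$n)) {
    p_g <- n_g / rowSums(n_g)
    pos <- n_g > 0
    stat <- stat + 2 * sum(n_g[pos] * log(p_g[pos] / p0[pos]))
  }
  stat <- max(stat, 0)
  g <- 2
  df <- switch(convention,
               standard = (g - 1) * m * (m - 1),
               paper_compatible = (g - 1) * (m^2 - 1))
  new_chain_test(statistic = stat, df = df,
                 method = "Kullback divergence test of chain homogeneity",
                 convention = convention,
                 data.name = paste(counts_a$group %||% "A", "vs",
                                   counts_b$group %||% "B"))
}

new_chain_test <- function(statistic, df, method, convention, data.name) {
  structure(
    list(statistic = c("G-squared" = statistic),
         parameter = c(df = df),
         p.value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
         method = paste0(method, " (df convention: ", convention, ")"),
         convention = convention,
         data.name = data.name),
    class = c("chain_test", "htest")
  )
}

#' Flag per-cell group differences by CI disjointness
#'
#' Marks a transition-matrix cell as differing between two groups when the
#' groups' confidence intervals for that cell do not overlap — the rule
#' behind the asterisks of published group-comparison transition tables.
#'
#' @param fit_a,fit_b `transition_fit` objects with the same state order
#'   and confidence level (e.g. from [estimate_transition_matrix()] or
#'   [transition_fit()]).
#' @return A tibble with one row per cell: `from`, `to`, estimates and
#'   intervals for both groups, and logical `flagged`.
#' @export
cell_difference_flags <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "transition_fit"),
            inherits(fit_b, "transition_fit"))
  if (!identical(fit_a$states, fit_b$states)) {
    stop("state orderings differ between the two fits", call. = FALSE)
  }
  if (!isTRUE(all.equal(fit_a$level, fit_b$level))) {
    stop("confidence levels differ between the two fits", call. = FALSE)
  }
  if (anyNA(fit_a$ci_low) || anyNA(fit_b$ci_low)) {
    stop("both fits need confidence intervals for every cell", call. = FALSE)
  }
  grid <- tidyr::expand_grid(from = fit_a$states, to = fit_a$states)
  flat <- function(m) as.vector(t(m))
  out <- dplyr::mutate(
    grid,
    estimate_a = flat(fit_a$p_hat), low_a = flat(fit_a$ci_low),
    high_a = flat(fit_a$ci_high),
    estimate_b = flat(fit_b$p_hat), low_b = flat(fit_b$ci_low),
    high_b = flat(fit_b$ci_high),
    flagged = .data$low_a > .data$high_b | .data$low_b > .data$high_a
  )
  attr(out, "rule") <- "CI-disjoint"
  out
}
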