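#' Two-sample t-test from summary statistics
#'
#' Compares two group means given only the published summaries
#' (mean, sample SD, n per group) — the usual situation when checking a
#' demographics table. The default is the pooled-variance Student t with
#' `df = n1 + n2 - 2`; `var_equal = FALSE` gives the Welch statistic and
#' Satterthwaite df. With equal group sizes the two statistics coincide.
#'
#' @param mean1,sd1,n1 Summary statistics for group 1.
#' @param mean2,sd2,n2 Summary statistics for group 2.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A one-row tibble: `estimate` (mean1 - mean2), `statistic`,
#'   `df`, `p.value`, `method`.
#' @export
#' @examples
#' t_test_summary(29.7, 4.84, 18, 30.7, 3.04, 18)
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    stop("degenerate variance: both group SDs are zero", call. = FALSE)
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t-test (pooled variance)"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t-test"
  }
  t_stat <- (mean1 - mean2) / se
  tibble::tibble(
    estimate = mean1 - mean2,
    statistic = t_stat,
    df = df,
    p.value = 2 * stats::pt(-abs(t_stat), df = df),
    method = method
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of independence in a 2x2 contingency table (e.g. gender by
#' group), using the point-probability two-sided convention: the p-value
#' sums the hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed one. A margin of
#' zero makes the distribution degenerate; the test then returns p = 1 with
#' a warning.
#'
#' @param x A 2x2 matrix of nonnegative integer counts (rows = groups,
#'   columns = categories).
#' @return A one-row tibble: `p.value`, `odds_ratio` (conditional MLE),
#'   `method`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(4, 14, 7, 11), 2, byrow = TRUE))
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2)) || any(x < 0) || any(x != round(x))) {
    stop("x must be a 2x2 matrix of nonnegative integer counts",
         call. = FALSE)
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warning("a zero margin makes the table degenerate; p = 1",
            call. = FALSE)
    return(tibble::tibble(p.value = 1, odds_ratio = NA_real_,
                          method = "Fisher's exact test (degenerate margin)"))
  }
  ft <- stats::fisher.test(x)
  tibble::tibble(
    p.value = ft$p.value,
    odds_ratio = unname(ft$estimate),
    method = "Fisher's exact test (two-sided)"
  )
}
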