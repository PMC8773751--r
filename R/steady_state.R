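#' Stationary (steady-state) distribution of a gaze chain
#'
#' Solves `pi %*% P = pi`, `sum(pi) = 1` for a row-stochastic transition
#' matrix. The stationary vector is the long-run occupancy of the AOI
#' states — the "attraction pattern" of the gaze process — and is unique
#' whenever the chain is irreducible, which is checked before solving.
#'
#' The default solver replaces one equation of the singular system
#' `t(P) - I` by the normalisation constraint and solves it directly;
#' `method = "power"` iterates `pi <- pi %*% P` to convergence and is kept
#' as an independent cross-check.
#'
#' @param P A 3x3 row-stochastic matrix, or a `transition_fit` (its `p_hat`
#'   is used).
#' @param tol Numerical tolerance for the row-stochasticity check and the
#'   residual check `max |pi P - pi|`.
#' @param method `"solve"` (direct linear solve) or `"power"`.
#' @return An object of class `steady_state`: a list with the named
#'   probability vector `pi`, the state labels and the matrix used.
#' @export
#' @examples
#' P <- matrix(c(0.43, 0.46, 0.11,
#'               0.18, 0.74, 0.08,
#'               0.25, 0.55, 0.20), 3, byrow = TRUE)
#' steady_state(P)$pi
steady_state <- function(P, tol = 1e-8, method = c("solve", "power")) {
  method <- match.arg(method)
  group <- NULL
  if (inherits(P, "transition_fit")) {
    group <- P$group
    P <- P$p_hat
  }
  P <- check_stochastic(P, tol = tol)
  if (!is_irreducible(P)) {
    stop("chain is reducible: the stationary distribution is not unique",
         call. = FALSE)
  }
  k <- n_states()
  pi <- switch(method,
    solve = {
      A <- t(P) - diag(k)
      A[k, ] <- 1
      b <- c(rep(0, k - 1), 1)
      as.numeric(solve(A, b))
    },
    power = {
      v <- rep(1 / k, k)
      for (iter in seq_len(100000L)) {
        v_new <- as.numeric(v %*% P)
        if (max(abs(v_new - v)) < 1e-14) { v <- v_new; break }
        v <- v_new
      }
      v / sum(v)
    }
  )
  pi[abs(pi) < 1e-12] <- pmax(pi[abs(pi) < 1e-12], 0)
  if (any(pi < 0)) {
    stop("stationary solve produced negative probabilities", call. = FALSE)
  }
  pi <- pi / sum(pi)
  resid <- max(abs(as.numeric(pi %*% P) - pi))
  if (resid > 1e-10) {
    stop("stationary vector failed the residual check (|pi P - pi| = ",
         signif(resid, 3), ")", call. = FALSE)
  }
  new_steady_state(pi = stats::setNames(pi, aoi_states()), P = P,
                   group = group, method = method)
}

new_steady_state <- function(pi, P = NULL, group = NULL, method = "solve",
                             ci_low = NULL, ci_high = NULL, level = NULL,
                             n_boot = NULL) {
  structure(
    list(pi = pi, states = aoi_states(), P = P, group = group,
         method = method, ci_low = ci_low, ci_high = ci_high, level = level,
         n_boot = n_boot),
    class = "steady_state"
  )
}

# Strong connectivity of the directed graph with edges where P > 0, via
# boolean reachability (enough at k = 3; no graph library needed).
is_irreducible <- function(P) {
  k <- nrow(P)
  A <- (P > 0) | diag(k) > 0
  R <- A
  for (i in seq_len(k)) R <- (R %*% A) > 0
  all(R)
}

#' @export
print.steady_state <- function(x, digits = 3, ...) {
  cat("Steady-state distribution",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  if (!is.null(x$ci_low)) {
    cat(sprintf("%d%% bootstrap CI (%d draws)\n",
                round(100 * x$level), x$n_boot))
    out <- sprintf("%.*f [%.*f-%.*f]", digits, x$pi, digits, x$ci_low,
                   digits, x$ci_high)
    names(out) <- x$states
    print(out, quote = FALSE)
  } else {
    print(round(x$pi, digits))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for the steady state
#'
#' Parametric multinomial bootstrap: each origin row of the observed count
#' matrix is resampled as `multinomial(row_total, p_hat_row)`, the chain is
#' re-estimated and its stationary vector recomputed; percentile intervals
#' are taken over the bootstrap draws. Draws that happen to produce a
#' reducible chain are redrawn (at most 100 retries each).
#'
#' @param counts A [transition_counts()] object or 3x3 count matrix.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap draws (>= 200; default 2000).
#' @param seed Optional integer seed for reproducibility.
#' @return A `steady_state` object with `ci_low` / `ci_high` vectors.
#' @export
steady_state_ci <- function(counts, level = 0.95, n_boot = 2000,
                            seed = NULL) {
  counts <- as_transition_counts(counts)
  stopifnot(n_boot >= 200)
  if (!is.null(seed)) set.seed(seed)
  fit <- estimate_transition_matrix(counts, level = level)
  point <- steady_state(fit$p_hat)
  row_totals <- fit$row_totals
  k <- n_states()

  draws <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    for (retry in seq_len(100L)) {
      n_b <- t(vapply(seq_len(k), function(i) {
        as.numeric(stats::rmultinom(1, row_totals[i], fit$p_hat[i, ]))
      }, numeric(k)))
      p_b <- n_b / rowSums(n_b)
      ok <- tryCatch({
        draws[b, ] <- steady_state(p_b)$pi
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      if (retry == 100L) {
        stop("bootstrap draw repeatedly produced a degenerate chain",
             call. = FALSE)
      }
    }
  }
  alpha <- 1 - level
  qs <- apply(draws, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new_steady_state(pi = point$pi, P = fit$p_hat, group = counts$group,
                   ci_low = stats::setNames(qs[1, ], aoi_states()),
                   ci_high = stats::setNames(qs[2, ], aoi_states()),
                   level = level, n_boot = n_boot)
}
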