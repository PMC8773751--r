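#' The three AOI gaze states
#'
#' The state space used throughout the package: a fixation is coded as
#' `FACE` when it hits the face area of interest, `OBJECT` when it hits any
#' of the object AOIs on the display, and `NO_STIMULUS` when it falls on the
#' monitor but inside no AOI. The order is fixed (`FACE`, `OBJECT`,
#' `NO_STIMULUS`) and matches the row/column order of every matrix the
#' package produces.
#'
#' @return Character vector of length 3 with the canonical state labels.
#' @export
#' @examples
#' aoi_states()
aoi_states <- function() c("FACE", "OBJECT", "NO_STIMULUS")

# Factor with the canonical level order; unknown labels error rather than
# silently becoming NA.
as_aoi_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), aoi_states())
  if (length(bad) > 0) {
    stop("unknown AOI state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = aoi_states())
}

n_states <- function() 3L

# Validate a row-stochastic matrix over the AOI states. Returns the matrix
# with canonical dimnames.
check_stochastic <- function(P, tol = 1e-8, arg = "P") {
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) != n_states() || ncol(P) != n_states()) {
    stop(arg, " must be a numeric ", n_states(), "x", n_states(), " matrix",
         call. = FALSE)
  }
  if (any(P < -tol)) {
    stop(arg, " has negative entries", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol)) {
    stop(arg, " is not row-stochastic: row sums ",
         paste(signif(rs, 6), collapse = ", "), call. = FALSE)
  }
  dimnames(P) <- list(aoi_states(), aoi_states())
  P
}

check_prob_vector <- function(p, tol = 1e-8, arg = "pi0") {
  p <- as.numeric(p)
  if (length(p) != n_states() || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(arg, " must be a length-", n_states(),
         " probability vector summing to 1", call. = FALSE)
  }
  stats::setNames(p, aoi_states())
}
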