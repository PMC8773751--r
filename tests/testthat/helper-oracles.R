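# Independent oracles and small fixture builders used across the suite.

# Reference group matrices, typed by hand so tests do not depend on the
# package's own copy.
ref_td <- function() {
  matrix(c(0.43, 0.46, 0.11,
           0.18, 0.74, 0.08,
           0.25, 0.55, 0.20), 3, byrow = TRUE,
         dimnames = list(aoi_states(), aoi_states()))
}
ref_asd <- function() {
  matrix(c(0.36, 0.49, 0.15,
           0.15, 0.70, 0.15,
           0.14, 0.37, 0.49), 3, byrow = TRUE,
         dimnames = list(aoi_states(), aoi_states()))
}

# Stationary distribution by plain power iteration (independent of the
# package's linear solve).
power_iter <- function(P, iter = 20000L) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iter)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# Brute-force pair counting over a single state vector.
pair_count_oracle <- function(states) {
  states <- as.character(states)
  n <- matrix(0, 3, 3, dimnames = list(aoi_states(), aoi_states()))
  if (length(states) < 2) return(n)
  for (t in seq_len(length(states) - 1)) {
    n[states[t], states[t + 1]] <- n[states[t], states[t + 1]] + 1
  }
  n
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration
# (point-probability convention).
fisher_enum <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal fixation-event tibble builder.
make_events <- function(states, participant = "p1", group = "G",
                        display = "d1", n_obj = 3) {
  states <- as.character(states)
  ev <- tibble::tibble(
    participant_id = participant,
    group = group,
    display_id = display,
    fixation_index = seq_along(states),
    aoi_face = states == "FACE"
  )
  for (k in seq_len(n_obj)) {
    ev[[paste0("aoi_obj_", k)]] <-
      states == "OBJECT" & ((seq_along(states) %% n_obj) + 1 == k)
  }
  ev
}

# Write a fixation TSV from raw text lines (for parser edge cases).
write_lines_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# One long simulated sequence as a sequence tibble.
sim_seq_tbl <- function(P, n, group = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state_sequence(simulate_sequence(P, "stationary", n), group = group)
}
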