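test_that("a deterministic cycle satisfies the order test exactly", {
  # F -> O -> N -> F ...: second-order conditionals equal first-order ones
  cyc <- rep(c("FACE", "OBJECT", "NO_STIMULUS"), 20)
  res <- verify_markov_property(state_sequence(cyc))
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
})

test_that("order test df follows the declared convention", {
  seqs <- sim_seq_tbl(ref_td(), 500, seed = 3)
  paper <- verify_markov_property(seqs, convention = "paper_compatible")
  std <- verify_markov_property(seqs, convention = "standard")
  expect_equal(unname(paper$parameter), 27)
  expect_equal(unname(std$parameter), 12)
  # same statistic, different reference distribution
  expect_equal(paper$statistic, std$statistic)
  expect_gt(std$p.value, 0)
})

test_that("sequences without triples are rejected", {
  seqs <- dplyr::bind_rows(
    state_sequence(c("FACE", "OBJECT"), display_id = "d1"),
    state_sequence(c("OBJECT", "FACE"), display_id = "d2")
  )
  expect_error(verify_markov_property(seqs), "too short")
})

test_that("planted second-order dynamics are detected", {
  # next state = state two steps back with prob 0.9, else uniform other
  set.seed(77)
  n <- 3000
  s <- integer(n)
  s[1:2] <- c(1, 2)
  for (t in 3:n) {
    s[t] <- if (stats::runif(1) < 0.9) s[t - 2] else sample(1:3, 1)
  }
  seqs <- state_sequence(aoi_states()[s])
  res <- verify_markov_property(seqs, convention = "standard")
  expect_lt(res$p.value, 0.001)
})

test_that("divergence of identical chains is zero with p = 1", {
  n <- matrix(c(40, 40, 20, 20, 60, 20, 25, 50, 25), 3, byrow = TRUE)
  res <- divergence_test(transition_counts(n, "A"),
                         transition_counts(n, "B"))
  expect_equal(unname(res$statistic), 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
  expect_equal(unname(res$parameter), 8)
  std <- divergence_test(transition_counts(n, "A"),
                         transition_counts(n, "B"),
                         convention = "standard")
  expect_equal(unname(std$parameter), 6)
})

test_that("divergence is symmetric, positive iff chains differ, linear in scale", {
  set.seed(21)
  for (rep in 1:5) {
    na <- matrix(rpois(9, 40) + 1, 3)
    nb <- matrix(rpois(9, 40) + 1, 3)
    a <- transition_counts(na, "A")
    b <- transition_counts(nb, "B")
    ab <- divergence_test(a, b)
    ba <- divergence_test(b, a)
    expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
    expect_gt(unname(ab$statistic), 0)
    # scaling both count matrices by c scales the statistic by c
    scaled <- divergence_test(transition_counts(3 * na, "A"),
                              transition_counts(3 * nb, "B"))
    expect_equal(unname(scaled$statistic), 3 * unname(ab$statistic),
                 tolerance = 1e-9)
    # equal row-normalised matrices give exactly zero
    prop <- divergence_test(transition_counts(na, "A"),
                            transition_counts(2 * na, "B"))
    expect_equal(unname(prop$statistic), 0, tolerance = 1e-12)
  }
})

test_that("divergence test input validation", {
  n <- matrix(c(40, 40, 20, 20, 60, 20, 25, 50, 25), 3, byrow = TRUE)
  expect_error(divergence_test(transition_counts(n, "A"),
                               transition_counts(n, "A")),
               "same group label")
  empty_row <- n
  empty_row[3, ] <- 0
  expect_error(divergence_test(transition_counts(n, "A"),
                               transition_counts(empty_row, "B")),
               "NO_STIMULUS")
})

test_that("cell flags fire exactly when group intervals are disjoint", {
  # published-style fits: intervals only, no raw counts
  td <- transition_fit(
    ref_td(),
    ci_low = matrix(c(0.40, 0.43, 0.09,
                      0.16, 0.71, 0.08,
                      0.21, 0.49, 0.17), 3, byrow = TRUE),
    ci_high = matrix(c(0.46, 0.50, 0.12,
                       0.19, 0.76, 0.10,
                       0.29, 0.60, 0.24), 3, byrow = TRUE),
    group = "TD")
  asd <- transition_fit(
    ref_asd(),
    ci_low = matrix(c(0.29, 0.41, 0.10,
                      0.13, 0.65, 0.12,
                      0.10, 0.30, 0.41), 3, byrow = TRUE),
    ci_high = matrix(c(0.43, 0.57, 0.19,
                       0.18, 0.76, 0.17,
                       0.18, 0.43, 0.57), 3, byrow = TRUE),
    group = "ASD")
  flags <- cell_difference_flags(td, asd)
  get <- function(f, t) flags$flagged[flags$from == f & flags$to == t]
  # the entire NO_STIMULUS row differs between groups
  expect_true(get("NO_STIMULUS", "NO_STIMULUS"))
  expect_true(get("NO_STIMULUS", "FACE"))
  expect_true(get("NO_STIMULUS", "OBJECT"))
  # FACE -> FACE intervals overlap: no flag
  expect_false(get("FACE", "FACE"))
  # OBJECT -> NO_STIMULUS is the remaining flagged cell
  expect_true(get("OBJECT", "NO_STIMULUS"))
  expect_equal(sum(flags$flagged), 4)

  none <- cell_difference_flags(td, td)
  expect_false(any(none$flagged))
})

test_that("chain tests are chi-square upper-tail and tidy()-able", {
  n <- matrix(c(40, 40, 20, 20, 60, 20, 25, 50, 25), 3, byrow = TRUE)
  res <- divergence_test(transition_counts(n + 5, "A"),
                         transition_counts(n, "B"))
  expect_equal(res$p.value,
               pchisq(unname(res$statistic), 8, lower.tail = FALSE))
  td <- tidy(res)
  expect_equal(td$df, 8)
  expect_equal(td$convention, "paper_compatible")
})
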