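test_that("degenerate chains simulate deterministically", {
  set.seed(1)
  s <- simulate_sequence(diag(3), c(1, 0, 0), 5)
  expect_equal(as.character(s), rep("FACE", 5))

  P <- matrix(c(0, 1, 0,
                0, 0, 1,
                1, 0, 0), 3, byrow = TRUE)
  set.seed(1)
  s2 <- simulate_sequence(P, c(1, 0, 0), 3)
  expect_equal(as.character(s2), c("FACE", "OBJECT", "NO_STIMULUS"))
})

test_that("long-run state frequencies converge to the steady state", {
  set.seed(314)
  s <- simulate_sequence(ref_asd(), "stationary", 2e5)
  freq <- as.numeric(table(s) / length(s))
  expect_equal(freq, power_iter(ref_asd()), tolerance = 0.01)
})

test_that("the default study design has the published dimensions", {
  cfg <- sim_config()
  expect_equal(cfg$n_participants_per_group, 18L)
  expect_equal(cfg$n_displays, 32L)
  expect_equal(names(cfg$group_specs), c("TD", "ASD"))
  expect_equal(cfg$fixations_per_display$mean, 10)
  expect_equal(cfg$fixations_per_display$min, 2L)

  fixed <- sim_config(fixations_per_display = list(kind = "fixed",
                                                   mean = 10))
  events <- simulate_study(fixed)
  expect_equal(nrow(events), 2 * 18 * 32 * 10)
  seqs <- build_sequences(events)
  expect_equal(nrow(dplyr::distinct(seqs, participant_id, display_id)),
               1152)
})

test_that("simulation is byte-identical under a seed and stable under growth", {
  cfg <- sim_config(n_participants_per_group = 3, n_displays = 4, seed = 7)
  e1 <- simulate_study(cfg)
  e2 <- simulate_study(cfg)
  expect_identical(e1, e2)

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(e1, p1)
  write_fixation_table(e2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # adding participants leaves earlier participants' data untouched
  bigger <- sim_config(n_participants_per_group = 5, n_displays = 4,
                       seed = 7)
  e3 <- simulate_study(bigger)
  kept <- dplyr::semi_join(e3, dplyr::distinct(e1, participant_id),
                           by = "participant_id")
  expect_identical(kept, e1)
})

test_that("invalid configs are rejected with named errors", {
  bad <- matrix(c(0.5, 0.5, 0.5, 0.2, 0.7, 0.1, 0.1, 0.2, 0.7), 3,
                byrow = TRUE)
  expect_error(
    sim_config(group_specs = list(G = list(transition_matrix = bad))),
    "transition_matrix for group G")
  expect_error(
    sim_config(group_specs = list(G = list(transition_matrix = ref_td(),
                                           initial_distribution = c(1, 1, 1)))),
    "initial_distribution for group G")
})

test_that("the bundled study config reproduces the default design", {
  path <- system.file("extdata", "study_config.yaml",
                      package = "scanmarkov")
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_participants_per_group, 18L)
  expect_equal(cfg$n_displays, 32L)
  expect_equal(cfg$group_specs$TD$transition_matrix, ref_td())
  expect_equal(cfg$group_specs$ASD$transition_matrix, ref_asd())
})

test_that("the full simulate -> estimate chain recovers the truth", {
  # longer displays than the default design so every origin row is well
  # populated (the rarest state holds ~10% of fixations)
  cfg <- sim_config(fixations_per_display = list(kind = "fixed", mean = 50),
                    seed = 20)
  events <- simulate_study(cfg)
  seqs <- build_sequences(events)
  for (g in c("TD", "ASD")) {
    truth <- gaze_reference_matrices()[[g]]
    cts <- count_transitions(seqs, group = g)
    expect_gte(cts$n_total, 5000)
    fit <- estimate_transition_matrix(cts)
    expect_lt(max(abs(fit$p_hat - truth)), 0.02)
  }
})
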