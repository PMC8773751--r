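test_that("a small fixation table parses in index order", {
  path <- write_lines_tsv(c(
    "participant_id\tgroup\tdisplay_id\tfixation_index\taoi_face\taoi_obj_1\taoi_obj_2\taoi_obj_3",
    "p1\tTD\td1\t2\t0\t1\t0\t0",
    "p1\tTD\td1\t1\ttrue\tfalse\tFALSE\t0",
    "p1\tTD\td1\t3\t0\t0\t0\t0"
  ))
  ev <- read_fixation_table(path)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$fixation_index, 1:3)
  expect_type(ev$aoi_face, "logical")
  expect_equal(ev$aoi_face, c(TRUE, FALSE, FALSE))
  expect_equal(ev$aoi_obj_1, c(FALSE, TRUE, FALSE))
})

test_that("an empty file with a valid header gives zero events", {
  path <- write_lines_tsv(
    "participant_id\tgroup\tdisplay_id\tfixation_index\taoi_face\taoi_obj_1")
  ev <- read_fixation_table(path)
  expect_equal(nrow(ev), 0)
})

test_that("parser errors name the offending column or row", {
  no_face <- write_lines_tsv(c(
    "participant_id\tgroup\tdisplay_id\tfixation_index\taoi_obj_1",
    "p1\tTD\td1\t1\t0"
  ))
  expect_error(read_fixation_table(no_face), "aoi_face")

  bad_bool <- write_lines_tsv(c(
    "participant_id\tgroup\tdisplay_id\tfixation_index\taoi_face\taoi_obj_1",
    "p1\tTD\td1\t1\t1\t0",
    "p1\tTD\td1\t2\tmaybe\t0"
  ))
  expect_error(read_fixation_table(bad_bool), "aoi_face.*row 2")

  dup_index <- write_lines_tsv(c(
    "participant_id\tgroup\tdisplay_id\tfixation_index\taoi_face\taoi_obj_1",
    "p1\tTD\td1\t1\t1\t0",
    "p1\tTD\td1\t1\t0\t1"
  ))
  expect_error(read_fixation_table(dup_index), "duplicate fixation_index")
})

test_that("state coding follows the FACE > OBJECT > NO_STIMULUS rule", {
  ev <- make_events(c("FACE", "OBJECT", "NO_STIMULUS"))
  coded <- code_states(ev)
  expect_equal(as.character(coded$state),
               c("FACE", "OBJECT", "NO_STIMULUS"))

  # face takes priority over a simultaneous object hit, with a warning
  both <- make_events("FACE")
  both$aoi_obj_1 <- TRUE
  expect_warning(coded <- code_states(both), "priority")
  expect_equal(as.character(coded$state), "FACE")

  # any single object column suffices
  obj2 <- make_events("NO_STIMULUS")
  obj2$aoi_obj_2 <- TRUE
  expect_equal(as.character(code_states(obj2)$state), "OBJECT")
})

test_that("sequences keep repeats and never span displays", {
  ev <- dplyr::bind_rows(
    make_events(c("FACE", "FACE", "OBJECT"), display = "d1"),
    make_events(c("NO_STIMULUS", "FACE"), display = "d2")
  )
  seqs <- build_sequences(ev)
  expect_equal(nrow(seqs), 5)
  d1 <- dplyr::filter(seqs, display_id == "d1")
  expect_equal(as.character(d1$state), c("FACE", "FACE", "OBJECT"))
  expect_equal(d1$position, 1:3)
  # no transition bridges d1 -> d2
  cts <- count_transitions(seqs)
  expect_equal(cts$n_total, 3)
  expect_equal(cts$n["OBJECT", "NO_STIMULUS"], 0)
})

test_that("transition counting matches hand counts and pools sequences", {
  one <- state_sequence(c("FACE", "OBJECT", "OBJECT", "NO_STIMULUS"))
  n <- count_transitions(one)$n
  expect_equal(n["FACE", "OBJECT"], 1)
  expect_equal(n["OBJECT", "OBJECT"], 1)
  expect_equal(n["OBJECT", "NO_STIMULUS"], 1)
  expect_equal(sum(n), 3)

  two <- dplyr::bind_rows(
    state_sequence(c("FACE", "FACE"), display_id = "d1"),
    state_sequence(c("FACE", "FACE"), display_id = "d2")
  )
  expect_equal(count_transitions(two)$n["FACE", "FACE"], 2)

  expect_error(count_transitions(state_sequence("FACE")),
               "no transitions observed")
})

test_that("counts are permutation-invariant and total length - blocks", {
  set.seed(101)
  for (rep in 1:5) {
    blocks <- lapply(1:6, function(b) {
      len <- sample(2:8, 1)
      state_sequence(sample(aoi_states(), len, replace = TRUE),
                     participant_id = sprintf("p%d", b %% 3),
                     display_id = sprintf("d%d", b))
    })
    seqs <- dplyr::bind_rows(blocks)
    cts <- count_transitions(seqs)
    expect_equal(cts$n_total, nrow(seqs) - length(blocks))
    shuffled <- seqs[sample(nrow(seqs)), ]
    expect_equal(count_transitions(shuffled)$n, cts$n)
  }
})

test_that("write -> read round-trips to identical state sequences", {
  cfg <- sim_config(n_participants_per_group = 2, n_displays = 3,
                    fixations_per_display = list(kind = "poisson_truncated",
                                                 mean = 6, min = 2),
                    seed = 99)
  events <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(events, path)
  back <- read_fixation_table(path)
  expect_equal(build_sequences(back), build_sequences(events))
})
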