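#' Read a fixation-event table
#'
#' Reads a tab-separated fixation export (one row per fixation event, in the
#' style of a Tobii Studio fixation table) into a tibble. Required columns
#' are `participant_id`, `group`, `display_id`, `fixation_index` and
#' `aoi_face`; any number of object-AOI hit columns are recognised by a
#' shared prefix (default `"aoi_obj_"`). Optional `duration_ms` / `onset_ms`
#' columns are kept if present. Hit flags accept `0/1`, `true/false` and
#' `TRUE/FALSE`.
#'
#' Rows are returned ordered by (`participant_id`, `display_id`,
#' `fixation_index`); a duplicated `fixation_index` within a
#' participant-display block is an error, since the index encodes the order
#' in which the eye tracker recorded the events.
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param object_prefix Prefix identifying object-AOI hit columns.
#' @return A tibble of fixation events with logical hit-flag columns.
#' @seealso [write_fixation_table()], [code_states()], [build_sequences()]
#' @export
read_fixation_table <- function(path, object_prefix = "aoi_obj_") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("participant_id", "group", "display_id", "fixation_index",
                "aoi_face")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("fixation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  obj_cols <- grep(paste0("^", object_prefix), names(raw), value = TRUE)

  events <- raw
  events$fixation_index <- parse_count(raw$fixation_index, "fixation_index")
  for (col in c("aoi_face", obj_cols)) {
    events[[col]] <- parse_hit(raw[[col]], col)
  }
  for (col in intersect(c("duration_ms", "onset_ms"), names(raw))) {
    events[[col]] <- as.numeric(raw[[col]])
  }

  events <- dplyr::arrange(events, .data$participant_id, .data$display_id,
                           .data$fixation_index)
  dup <- dplyr::summarise(
    dplyr::group_by(events, .data$participant_id, .data$display_id),
    dup = anyDuplicated(.data$fixation_index) > 0, .groups = "drop"
  )
  if (any(dup$dup)) {
    bad <- dup[dup$dup, ]
    stop("duplicate fixation_index within block(s): ",
         paste(bad$participant_id, bad$display_id, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  events
}

parse_hit <- function(x, col) {
  x_low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x_low %in% c("1", "true")] <- TRUE
  out[x_low %in% c("0", "false")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop("non-boolean value ", sQuote(x[bad[1]]), " in column ", col,
         " at data row ", bad[1], call. = FALSE)
  }
  as.logical(out)
}

parse_count <- function(x, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | out <= 0)
  if (length(bad) > 0) {
    stop("column ", col, " must hold positive integers; offending data row ",
         bad[1], call. = FALSE)
  }
  out
}

#' Write a fixation-event table
#'
#' Writes fixation events in the tab-separated dialect that
#' [read_fixation_table()] reads back exactly (logicals as `TRUE`/`FALSE`).
#'
#' @param events Tibble of fixation events (e.g. from [simulate_study()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fixation_table <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Code fixation events into AOI states
#'
#' Adds a `state` column to a fixation-event tibble following the coding
#' rule: `FACE` if the face AOI was hit, otherwise `OBJECT` if any object
#' AOI was hit, otherwise `NO_STIMULUS`. With non-overlapping elliptical
#' AOIs a fixation should hit at most one AOI; if a row hits both the face
#' and an object AOI the face takes priority and a warning reports how many
#' rows were affected.
#'
#' @param events Tibble of fixation events.
#' @param object_prefix Prefix identifying object-AOI hit columns.
#' @return The input tibble with an added `state` factor column.
#' @export
code_states <- function(events, object_prefix = "aoi_obj_") {
  obj_cols <- grep(paste0("^", object_prefix), names(events), value = TRUE)
  any_object <- if (length(obj_cols) == 0) {
    rep(FALSE, nrow(events))
  } else {
    rowSums(as.matrix(events[obj_cols])) > 0
  }
  face <- as.logical(events$aoi_face)
  conflict <- face & any_object
  if (any(conflict)) {
    warning(sum(conflict), " fixation(s) hit both the face and an object AOI;",
            " coded as FACE by priority", call. = FALSE)
  }
  state <- dplyr::case_when(face ~ "FACE",
                            any_object ~ "OBJECT",
                            TRUE ~ "NO_STIMULUS")
  dplyr::mutate(events, state = as_aoi_factor(state))
}

#' Build per-participant, per-display state sequences
#'
#' Segments coded fixation events into ordered AOI state sequences, one per
#' (participant, display) block. Consecutive fixations in the same AOI are
#' kept as separate elements — they become the self-transitions that
#' dominate the diagonal of gaze transition matrices. Sequences never span
#' two displays (a central fixation cross between displays resets gaze).
#'
#' @param events Tibble of fixation events; a `state` column is added with
#'   [code_states()] if absent.
#' @param object_prefix Passed to [code_states()] when coding is needed.
#' @return A tibble with columns `participant_id`, `group`, `display_id`,
#'   `position` (1-based order within the block) and `state`.
#' @export
build_sequences <- function(events, object_prefix = "aoi_obj_") {
  if (!"state" %in% names(events)) {
    events <- code_states(events, object_prefix = object_prefix)
  }
  events |>
    dplyr::arrange(.data$participant_id, .data$display_id,
                   .data$fixation_index) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$display_id) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "group", "display_id", "position",
                  "state") |>
    dplyr::mutate(state = as_aoi_factor(.data$state))
}

#' Assemble a state-sequence tibble from a vector of states
#'
#' Convenience constructor turning a bare vector of AOI state labels into
#' the sequence-tibble layout used by [count_transitions()] and the chain
#' tests, as a single (participant, display) block.
#'
#' @param states Character or factor vector of AOI state labels.
#' @param participant_id,group,display_id Identifiers for the block.
#' @return A one-block sequence tibble.
#' @export
#' @examples
#' state_sequence(c("FACE", "OBJECT", "OBJECT", "NO_STIMULUS"))
state_sequence <- function(states, participant_id = "p1", group = "sim",
                           display_id = "d1") {
  tibble::tibble(
    participant_id = participant_id,
    group = group,
    display_id = display_id,
    position = seq_along(states),
    state = as_aoi_factor(states)
  )
}

#' Write state sequences as TSV
#'
#' @param sequences Sequence tibble from [build_sequences()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sequence_table <- function(sequences, path) {
  out <- dplyr::mutate(sequences, state = as.character(.data$state))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
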