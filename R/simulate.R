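#' Reference gaze transition matrices for the two toddler groups
#'
#' The published 3x3 AOI transition matrices (point estimates) for
#' typically developing toddlers (`TD`) and toddlers with autism spectrum
#' disorder (`ASD`) in a face-among-objects visual-search paradigm. They
#' serve as the default ground truth of the synthetic study generator and
#' as worked-example inputs: their stationary distributions are roughly
#' (0.25, 0.65, 0.10) for TD and (0.19, 0.59, 0.22) for ASD over
#' (FACE, OBJECT, NO_STIMULUS).
#'
#' @return A named list of two row-stochastic matrices, `TD` and `ASD`.
#' @export
#' @examples
#' steady_state(gaze_reference_matrices()$TD)$pi
gaze_reference_matrices <- function() {
  td <- matrix(c(0.43, 0.46, 0.11,
                 0.18, 0.74, 0.08,
                 0.25, 0.55, 0.20), 3, byrow = TRUE)
  asd <- matrix(c(0.36, 0.49, 0.15,
                  0.15, 0.70, 0.15,
                  0.14, 0.37, 0.49), 3, byrow = TRUE)
  dimnames(td) <- dimnames(asd) <- list(aoi_states(), aoi_states())
  list(TD = td, ASD = asd)
}

#' Configure a synthetic two-group fixation study
#'
#' Describes the design of a simulated eye-tracking study: per-group
#' ground-truth transition matrices, participants per group, displays per
#' participant and the distribution of fixations per display. Defaults
#' mirror the two-group toddler design the package models: 18 participants
#' per group viewing 32 five-second displays, with a truncated-Poisson
#' (mean 10, minimum 2) number of fixations per display and the
#' [gaze_reference_matrices()] as ground truth.
#'
#' @param group_specs Named list, one entry per group, each a list with
#'   `transition_matrix` (3x3 row-stochastic) and `initial_distribution`
#'   (length-3 probability vector, or `"stationary"` to start each display
#'   from the chain's steady state — the between-display fixation cross
#'   carries no AOI information).
#' @param n_participants_per_group Participants per group (default 18).
#' @param n_displays Displays per participant (default 32). The first half
#'   carry 3 object AOIs and the second half 5, mirroring 4-item and 6-item
#'   display sets.
#' @param fixations_per_display List with `kind` (`"fixed"` or
#'   `"poisson_truncated"`), `mean`, and (for the truncated kind) `min`.
#' @param seed Integer seed; the generator derives one child seed per
#'   (group, participant, display), so enlarging the design never perturbs
#'   previously generated units.
#' @return A `sim_config` object.
#' @export
sim_config <- function(group_specs = NULL,
                       n_participants_per_group = 18,
                       n_displays = 32,
                       fixations_per_display = list(kind = "poisson_truncated",
                                                    mean = 10, min = 2),
                       seed = 1) {
  if (is.null(group_specs)) {
    ref <- gaze_reference_matrices()
    group_specs <- lapply(ref, function(P) {
      list(transition_matrix = P, initial_distribution = "stationary")
    })
  }
  if (is.null(names(group_specs)) || any(names(group_specs) == "")) {
    stop("group_specs must be a named list (one entry per group)",
         call. = FALSE)
  }
  group_names <- names(group_specs)
  group_specs <- lapply(group_names, function(g) {
    spec <- group_specs[[g]]
    spec$transition_matrix <- check_stochastic(
      spec$transition_matrix, tol = 1e-9,
      arg = paste0("transition_matrix for group ", g))
    init <- spec$initial_distribution %||% "stationary"
    if (!identical(init, "stationary")) {
      init <- check_prob_vector(init, arg = paste0(
        "initial_distribution for group ", g))
    }
    spec$initial_distribution <- init
    spec
  })
  names(group_specs) <- group_names
  stopifnot(n_participants_per_group >= 1, n_displays >= 1)
  fix <- fixations_per_display
  fix$kind <- match.arg(fix$kind %||% "poisson_truncated",
                        c("fixed", "poisson_truncated"))
  fix$mean <- fix$mean %||% 10
  fix$min <- as.integer(fix$min %||% 2L)
  stopifnot(fix$mean > 0, fix$min >= 1)
  structure(
    list(group_specs = group_specs,
         n_participants_per_group = as.integer(n_participants_per_group),
         n_displays = as.integer(n_displays),
         fixations_per_display = fix,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' @param path YAML file mirroring the [sim_config()] fields (`groups`,
#'   `n_participants_per_group`, `n_displays`, `fixations_per_display`,
#'   `seed`); see the bundled `study_config.yaml` in `inst/extdata` for the
#'   study-scale example.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("config is missing `groups`", call. = FALSE)
  specs <- lapply(cfg$groups, function(gs) {
    P <- gs$transition_matrix
    if (is.list(P)) P <- do.call(rbind, P)
    list(transition_matrix = P,
         initial_distribution = gs$initial_distribution %||% "stationary")
  })
  sim_config(
    group_specs = specs,
    n_participants_per_group = cfg$n_participants_per_group %||% 18,
    n_displays = cfg$n_displays %||% 32,
    fixations_per_display = cfg$fixations_per_display %||%
      list(kind = "poisson_truncated", mean = 10, min = 2),
    seed = cfg$seed %||% 1
  )
}

# Lehmer-style deterministic seed derivation: one child seed per index
# tuple, all < 2^31 - 1. Keeps earlier units' streams fixed when the design
# grows.
child_seed <- function(seed, ...) {
  mix <- function(x) (x * 48271) %% 2147483647
  s <- mix((abs(seed) %% 2147483646) + 1)
  for (i in c(...)) {
    s <- mix((s + (i %% 65536) * 32749 + 1) %% 2147483647)
  }
  as.integer(s)
}

#' Simulate one first-order AOI state sequence
#'
#' Draws the first state from `pi0` and each subsequent state from the row
#' of `P` indexed by the current state, using the current RNG stream
#' (seed with `set.seed()` for reproducibility).
#'
#' @param P 3x3 row-stochastic transition matrix.
#' @param pi0 Length-3 initial distribution, or `"stationary"` for the
#'   stationary distribution of `P`.
#' @param length Sequence length (>= 1).
#' @return A factor vector of AOI states with the canonical levels.
#' @export
#' @examples
#' set.seed(1)
#' simulate_sequence(gaze_reference_matrices()$TD, "stationary", 10)
simulate_sequence <- function(P, pi0 = "stationary", length) {
  P <- check_stochastic(P, tol = 1e-9)
  if (identical(pi0, "stationary")) pi0 <- steady_state(P)$pi
  pi0 <- check_prob_vector(pi0)
  stopifnot(length >= 1)
  # cumulative cut points; third column is 1 by row-stochasticity
  c1 <- P[, 1]
  c2 <- P[, 1] + P[, 2]
  u <- stats::runif(length)
  s <- integer(length)
  s[1] <- 1L + (u[1] > pi0[1]) + (u[1] > pi0[1] + pi0[2])
  if (length > 1) {
    for (t in 2:length) {
      prev <- s[t - 1L]
      s[t] <- 1L + (u[t] > c1[prev]) + (u[t] > c2[prev])
    }
  }
  factor(aoi_states()[s], levels = aoi_states())
}

#' Simulate a full two-group fixation study
#'
#' Generates a complete fixation-event table under a [sim_config()]:
#' for every (group, participant, display) cell a sequence length is drawn,
#' a first-order chain is simulated from the group's matrix, and the states
#' are materialised as fixation events (`FACE` sets the face hit flag;
#' `OBJECT` sets one uniformly chosen object-AOI flag; `NO_STIMULUS` sets
#' none). Fully deterministic given the config seed.
#'
#' @param config A `sim_config` object (default: the study-scale design).
#' @return A fixation-event tibble in the [read_fixation_table()] dialect
#'   (object columns `aoi_obj_1` ... up to the largest AOI count used).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$group_specs)
  n_part <- config$n_participants_per_group
  n_disp <- config$n_displays
  fix <- config$fixations_per_display
  # 4-item displays (3 object AOIs) in the first half, 6-item (5) after
  n_obj_for_display <- function(d) if (d <= ceiling(n_disp / 2)) 3L else 5L
  max_obj <- max(vapply(seq_len(n_disp), n_obj_for_display, integer(1)))

  # resolve "stationary" starts once per group
  inits <- lapply(config$group_specs, function(spec) {
    if (identical(spec$initial_distribution, "stationary")) {
      steady_state(spec$transition_matrix)$pi
    } else {
      spec$initial_distribution
    }
  })

  blocks <- vector("list", length(groups) * n_part * n_disp)
  idx <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    P <- config$group_specs[[g]]$transition_matrix
    pi0 <- inits[[g]]
    for (p in seq_len(n_part)) {
      pid <- sprintf("%s_%02d", g, p)
      for (d in seq_len(n_disp)) {
        set.seed(child_seed(config$seed, gi, p, d))
        len <- switch(fix$kind,
          fixed = as.integer(round(fix$mean)),
          poisson_truncated = {
            repeat {
              l <- stats::rpois(1, fix$mean)
              if (l >= fix$min) break
            }
            l
          })
        states <- simulate_sequence(P, pi0, len)
        n_obj <- n_obj_for_display(d)
        obj_hit <- matrix(FALSE, len, max_obj)
        is_obj <- states == "OBJECT"
        if (any(is_obj)) {
          cols <- sample.int(n_obj, sum(is_obj), replace = TRUE)
          obj_hit[cbind(which(is_obj), cols)] <- TRUE
        }
        block <- tibble::tibble(
          participant_id = pid,
          group = g,
          display_id = sprintf("disp_%02d", d),
          fixation_index = seq_len(len),
          aoi_face = states == "FACE"
        )
        for (k in seq_len(max_obj)) {
          block[[paste0("aoi_obj_", k)]] <- obj_hit[, k]
        }
        idx <- idx + 1L
        blocks[[idx]] <- block
      }
    }
  }
  dplyr::bind_rows(blocks)
}
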