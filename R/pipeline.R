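#' Pipeline commands
#'
#' `run_simulate()`, `run_estimate()`, `run_compare()` and `run_baseline()`
#' tie the package's stages into file-in / file-out steps suitable for
#' scripted pipelines (a thin command-line wrapper lives in
#' `inst/cli/scanmarkov.R`). Every command writes its outputs plus a JSON
#' run manifest (`<out>.manifest.json`) recording the command, a digest of
#' its configuration, the seed, input and output paths and the package
#' version, so a run can be reproduced exactly.
#'
#' @name pipeline
#' @return Each command returns (invisibly) a list with its parsed results
#'   and the manifest.
NULL

write_manifest <- function(command, config, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config_digest = digest::digest(config),
    seed = seed,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    package_version = as.character(utils::packageVersion("scanmarkov"))
  )
  path <- paste0(outputs[[1]], ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @rdname pipeline
#' @param config A [sim_config()] object or the path to a YAML config file.
#' @param out Output path for the fixation TSV.
#' @param seed Optional integer overriding the config seed.
#' @export
run_simulate <- function(config = sim_config(), out, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  events <- simulate_study(config)
  write_fixation_table(events, out)
  manifest <- write_manifest("simulate", config, config$seed,
                             inputs = character(), outputs = out)
  message(nrow(events), " fixation events written to ", out)
  invisible(list(events = events, manifest = manifest))
}

#' @rdname pipeline
#' @param input Path to a fixation TSV in the [read_fixation_table()]
#'   dialect.
#' @param group Group label to estimate (must appear in the data).
#' @param level Confidence level (default 0.95).
#' @param se_mode Standard-error mode, `"paper"` or `"binomial"`.
#' @param n_boot Bootstrap draws for the steady-state CI; 0 skips the
#'   bootstrap.
#' @export
run_estimate <- function(input, group, out, level = 0.95,
                         se_mode = "paper", n_boot = 1000, seed = NULL) {
  events <- read_fixation_table(input)
  if (!group %in% unique(events$group)) {
    stop("unknown group label: ", group, call. = FALSE)
  }
  seqs <- build_sequences(events)
  counts <- count_transitions(seqs, group = group)
  fit <- estimate_transition_matrix(counts, level = level,
                                    se_mode = se_mode)
  ss <- if (n_boot >= 200) {
    steady_state_ci(counts, level = level, n_boot = n_boot, seed = seed)
  } else {
    steady_state(fit)
  }
  bundle <- list(
    group = group,
    states = aoi_states(),
    n_transitions = sum(counts$n),
    transition_matrix = fit_to_list(fit),
    steady_state = steady_to_list(ss),
    departure = as.list(stats::setNames(1 - diag(fit$p_hat), aoi_states()))
  )
  jsonlite::write_json(bundle, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  tsv_path <- sub("\\.json$", ".tsv", out)
  if (identical(tsv_path, out)) tsv_path <- paste0(out, ".tsv")
  write_matrix_tsv(fit, tsv_path)
  manifest <- write_manifest("estimate",
                             list(group = group, level = level,
                                  se_mode = se_mode, n_boot = n_boot),
                             seed, inputs = input,
                             outputs = c(out, tsv_path))
  invisible(list(fit = fit, steady_state = ss, manifest = manifest))
}

#' @rdname pipeline
#' @param group_a,group_b The two group labels to compare.
#' @param convention df convention for the chain tests,
#'   `"paper_compatible"` or `"standard"`.
#' @export
run_compare <- function(input, group_a, group_b, out, level = 0.95,
                        se_mode = "paper",
                        convention = "paper_compatible", seed = NULL) {
  events <- read_fixation_table(input)
  for (g in c(group_a, group_b)) {
    if (!g %in% unique(events$group)) {
      stop("unknown group label: ", g, call. = FALSE)
    }
  }
  seqs <- build_sequences(events)
  seqs_a <- dplyr::filter(seqs, .data$group == group_a)
  seqs_b <- dplyr::filter(seqs, .data$group == group_b)
  counts_a <- count_transitions(seqs_a, group = group_a)
  counts_b <- count_transitions(seqs_b, group = group_b)
  fit_a <- estimate_transition_matrix(counts_a, level = level,
                                      se_mode = se_mode)
  fit_b <- estimate_transition_matrix(counts_b, level = level,
                                      se_mode = se_mode)
  div <- divergence_test(counts_a, counts_b, convention = convention)
  mk_a <- verify_markov_property(seqs_a, convention = convention)
  mk_b <- verify_markov_property(seqs_b, convention = convention)
  flags <- cell_difference_flags(fit_a, fit_b)
  bundle <- list(
    groups = c(group_a, group_b),
    states = aoi_states(),
    divergence_test = test_to_list(div),
    markov_property = stats::setNames(
      list(test_to_list(mk_a), test_to_list(mk_b)), c(group_a, group_b)),
    transition_matrices = stats::setNames(
      list(fit_to_list(fit_a), fit_to_list(fit_b)), c(group_a, group_b)),
    steady_states = stats::setNames(
      list(steady_to_list(steady_state(fit_a)),
           steady_to_list(steady_state(fit_b))), c(group_a, group_b)),
    departure = stats::setNames(
      list(as.list(stats::setNames(1 - diag(fit_a$p_hat), aoi_states())),
           as.list(stats::setNames(1 - diag(fit_b$p_hat), aoi_states()))),
      c(group_a, group_b)),
    cell_difference_flags = flags
  )
  jsonlite::write_json(bundle, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- write_manifest("compare",
                             list(groups = c(group_a, group_b),
                                  level = level, se_mode = se_mode,
                                  convention = convention),
                             seed, inputs = input, outputs = out)
  invisible(list(divergence = div, markov_property = list(mk_a, mk_b),
                 fits = list(fit_a, fit_b), flags = flags,
                 manifest = manifest))
}

#' @rdname pipeline
#' @param age_col,sex_col Column names in the participant metadata TSV
#'   (one row per participant with a `group` column).
#' @export
run_baseline <- function(input, out, age_col = "age_months",
                         sex_col = "sex") {
  meta <- readr::read_tsv(input, col_types = readr::cols(),
                          progress = FALSE)
  for (col in c("group", age_col, sex_col)) {
    if (!col %in% names(meta)) {
      stop("metadata is missing column: ", col, call. = FALSE)
    }
  }
  groups <- sort(unique(meta$group))
  if (length(groups) != 2) {
    stop("metadata must contain exactly two groups", call. = FALSE)
  }
  g1 <- meta[meta$group == groups[1], ]
  g2 <- meta[meta$group == groups[2], ]
  tt <- t_test_summary(mean(g1[[age_col]]), stats::sd(g1[[age_col]]),
                       nrow(g1),
                       mean(g2[[age_col]]), stats::sd(g2[[age_col]]),
                       nrow(g2))
  tab <- table(meta$group, meta[[sex_col]])
  ft <- fisher_exact_2x2(unclass(tab))
  bundle <- list(groups = groups,
                 age_t_test = as.list(tt),
                 sex_fisher_test = as.list(ft))
  jsonlite::write_json(bundle, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- write_manifest("baseline", list(age_col = age_col,
                                              sex_col = sex_col),
                             NULL, inputs = input, outputs = out)
  invisible(list(age = tt, sex = ft, manifest = manifest))
}

fit_to_list <- function(fit) {
  list(p_hat = unname(split(fit$p_hat, row(fit$p_hat))),
       se = unname(split(fit$se, row(fit$se))),
       ci_low = unname(split(fit$ci_low, row(fit$ci_low))),
       ci_high = unname(split(fit$ci_high, row(fit$ci_high))),
       level = fit$level, se_mode = fit$se_mode,
       row_totals = as.list(stats::setNames(fit$row_totals, aoi_states())))
}

steady_to_list <- function(ss) {
  out <- list(pi = as.list(ss$pi))
  if (!is.null(ss$ci_low)) {
    out$ci_low <- as.list(ss$ci_low)
    out$ci_high <- as.list(ss$ci_high)
    out$level <- ss$level
    out$n_boot <- ss$n_boot
  }
  out
}

test_to_list <- function(tst) {
  list(test = tst$method, statistic = unname(tst$statistic),
       df = unname(tst$parameter), p_value = tst$p.value,
       convention = tst$convention)
}

# Table-layout TSV: one row per origin state, cells "0.43 [0.40-0.46]"
write_matrix_tsv <- function(fit, path) {
  cells <- matrix(sprintf("%.2f [%.2f-%.2f]", fit$p_hat, fit$ci_low,
                          fit$ci_high),
                  n_states(), dimnames = dimnames(fit$p_hat))
  df <- tibble::as_tibble(cells, rownames = "from")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
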