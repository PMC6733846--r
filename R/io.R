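#' Read and write spike tables
#'
#' Spike tables are headered TSV files with columns `cell_id`, `time_s` and
#' optionally `region`. On read, times are validated and sorted within cell
#' (with a warning when re-sorting was needed); malformed rows are reported
#' with their line numbers.
#'
#' @param path File path.
#' @return A spike-table tibble.
#' @export
read_spike_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    warn(sprintf("Malformed rows at line(s): %s.", paste(probs$row, collapse = ", ")))
  }
  if (!all(c("cell_id", "time_s") %in% names(x))) {
    abort("A spike table needs columns cell_id and time_s.")
  }
  if (nrow(x) == 0) {
    warn("Empty spike table.")
    return(as_tibble(x))
  }
  if (!is.numeric(x$time_s)) abort("`time_s` must be numeric.")
  assert_spike_table(x)
  sorted <- x |> group_by(.data$cell_id) |>
    mutate(.ok = !is.unsorted(.data$time_s)) |> ungroup()
  if (!all(sorted$.ok)) {
    warn("Spike times were not sorted within cell; sorting.")
  }
  x |> dplyr::arrange(.data$cell_id, .data$time_s)
}

#' @rdname read_spike_table
#' @param spikes A spike-table tibble.
#' @export
write_spike_table <- function(spikes, path) {
  assert_spike_table(spikes)
  readr::write_tsv(spikes, path, progress = FALSE)
  invisible(path)
}

#' Read and write stimulus-event tables
#'
#' Headered TSV with columns `train_id`, `stim_index`, `time_s`.
#'
#' @param path File path.
#' @return A tibble of stimulus events.
#' @export
read_stim_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("train_id", "stim_index", "time_s") %in% names(x))) {
    abort("A stimulus table needs train_id, stim_index, time_s.")
  }
  x
}

#' @rdname read_stim_table
#' @param events A stimulus-event tibble (or realised [stim_protocol()]).
#' @export
write_stim_table <- function(events, path) {
  if (inherits(events, "stim_protocol")) events <- events$events
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Read and write behavior traces
#'
#' Headered CSV with columns `trial_id`, `time_s`, `position_cm`.
#'
#' @param path File path.
#' @return A long trace tibble.
#' @export
read_behavior_trace <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("trial_id", "time_s", "position_cm") %in% names(x))) {
    abort("A behavior trace needs trial_id, time_s, position_cm.")
  }
  x
}

#' @rdname read_behavior_trace
#' @param trace A long trace tibble or `behavior_session`.
#' @export
write_behavior_trace <- function(trace, path) {
  trace <- as_behavior_trace(trace, arg = "trace")
  readr::write_csv(trace, path, progress = FALSE)
  invisible(path)
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes simulate -> response profiling -> silhouette -> decoding ->
#' behavior -> spike-behavior correlation on synthetic data, writing stage
#' outputs (CSV/TSV) and a JSON summary with the configuration echo. Stages can
#' be skipped; all randomness derives from `config$seed`.
#'
#' @param config A named list (or path to a YAML file). Recognised entries:
#'   `seed` (integer), `out_dir` (directory for outputs; created), `stages`
#'   (character subset of `c("simulate", "peth", "silhouette", "decode",
#'   "behavior", "correlate")`), `n_cells`, `n_trains`, `n_trials`,
#'   `decode_sizes`, `decode_repeats`, `silhouette_random`.
#' @return Invisibly, a list with the stage results and the summary.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("Reading YAML configs needs the yaml package.")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(seed = 1L, out_dir = NULL,
         stages = c("simulate", "peth", "silhouette", "decode", "behavior", "correlate"),
         n_cells = 60, n_trains = 50, n_trials = 60,
         decode_sizes = c(10, 30, 60), decode_repeats = 5,
         silhouette_random = 20),
    config)
  seed <- as.integer(cfg$seed)
  out <- list(config = cfg)
  save_csv <- function(x, name) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(x, file.path(cfg$out_dir, name), progress = FALSE)
    }
  }
  summary <- list(seed = seed)

  protocol <- generate_protocol(stim_protocol(n_trains = cfg$n_trains), seed = seed)
  if ("simulate" %in% cfg$stages) {
    pop <- population_spec(n_cells = cfg$n_cells, structure = "sequential", seed = seed)
    out$spikes <- generate_population_spikes(pop, protocol, seed = seed)
    out$session <- generate_behavior_session(
      behavior_spec(n_trials = cfg$n_trials, seed = seed))
    if (!is.null(cfg$out_dir)) {
      write_spike_table(out$spikes, file.path(cfg$out_dir, "spikes.tsv"))
      write_stim_table(protocol, file.path(cfg$out_dir, "stimuli.tsv"))
      write_behavior_trace(out$session, file.path(cfg$out_dir, "behavior.csv"))
    }
    summary$n_spikes <- nrow(out$spikes)
  }
  if ("peth" %in% cfg$stages) {
    if (is.null(out$spikes)) abort("Stage 'peth' needs the simulate stage (or preloaded spikes).")
    out$profiles <- response_profiles(out$spikes, protocol$events$time_s)
    ls <- latency_summary(out$profiles)
    save_csv(out$profiles, "response_profiles.csv")
    summary$responsive_pct <- ls$summary$responsive_pct[1]
    summary$median_latency_ms <- ls$summary$median_latency_ms[1]
  }
  pv <- NULL
  if (any(c("silhouette", "decode") %in% cfg$stages)) {
    if (is.null(out$spikes)) abort("Population stages need the simulate stage.")
    pv <- bin_population(out$spikes, protocol)
  }
  if ("silhouette" %in% cfg$stages) {
    traj <- pca_trajectories(pv)
    states <- extract_stimulus_states(traj, protocol)
    out$silhouette <- silhouette_analysis(states, n_random = cfg$silhouette_random,
                                          seed = seed)
    save_csv(tidy(out$silhouette), "silhouette.csv")
    summary$observed_mean_sc <- out$silhouette$observed_mean
    summary$n_states <- nrow(states)
  }
  if ("decode" %in% cfg$stages) {
    out$curve <- population_size_curve(pv, sizes = cfg$decode_sizes,
                                       n_repeats = cfg$decode_repeats, seed = seed)
    save_csv(out$curve, "decoding_curve.csv")
    top <- summarise_size_curve(out$curve)
    summary$decoding_median_accuracy <- top$median[which.max(top$n_cells)]
  }
  if ("behavior" %in% cfg$stages) {
    if (is.null(out$session)) abort("Stage 'behavior' needs the simulate stage.")
    out$session_metrics <- session_summary(out$session)
    out$stereotypy <- stereotypy_index(out$session)
    save_csv(out$session_metrics, "session_metrics.csv")
    summary$percent_correct <- out$session_metrics$percent_correct
    summary$stereotypy_index <- out$stereotypy$index
  }
  if ("correlate" %in% cfg$stages) {
    if (is.null(out$spikes)) abort("Stage 'correlate' needs the simulate stage.")
    dur <- protocol_duration(protocol)
    limb <- generate_forelimb_trace(duration = dur, seed = seed)
    trials <- tibble(trial_id = 1L, start_s = 0, end_s = dur)
    one_cell <- out$spikes |> filter(.data$cell_id == .data$cell_id[1])
    rates <- execution_rates(one_cell, trials)
    out$neurobeh <- spike_position_correlation(rates, limb)
    save_csv(out$neurobeh, "spike_position_correlation.csv")
    summary$example_cell_r <- out$neurobeh$r[1]
  }
  out$summary <- summary
  if (!is.null(cfg$out_dir)) {
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
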