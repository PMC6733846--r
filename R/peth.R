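#' Build a peri-event time histogram for one cell
#'
#' Spike times are aligned to each event and counted in half-open bins
#' `[edge, edge + bin_width)` at 1-ms resolution by default, over a window from
#' 1 s before to 300 ms after the event. Counts are summed across events, so
#' `sum(counts)` equals the number of aligned spikes falling in the window.
#'
#' @param spikes Numeric vector of spike times (s) for one cell, or a spike
#'   table restricted to one cell.
#' @param events Numeric vector of event (stimulus) times, s. At least one.
#' @param window Length-2 numeric window relative to the event, ms.
#' @param bin_width Bin width, ms; must divide the window length.
#' @param baseline_window Window (ms) used for baseline statistics; must lie
#'   within `window`.
#'
#' @return A `peth` object: list with `counts`, `bin_starts` (ms, left edges),
#'   `bin_width`, `window`, `n_events`, `baseline_window`.
#' @export
build_peth <- function(spikes, events, window = c(-1000, 300), bin_width = 1,
                       baseline_window = c(-1000, 0)) {
  if (is.data.frame(spikes)) {
    assert_spike_table(spikes)
    if (length(unique(spikes$cell_id)) > 1) {
      abort("`spikes` contains several cells; build one PETH per cell (see response_profiles()).")
    }
    spikes <- spikes$time_s
  }
  if (length(events) < 1) abort("`events` must contain at least one event time.")
  span <- diff(window)
  n_bins <- span / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("`bin_width` must divide the window length exactly.")
  }
  n_bins <- as.integer(round(n_bins))
  edges <- window[1] + bin_width * (0:n_bins)
  counts <- integer(n_bins)
  spikes <- sort(spikes)
  for (ev in events) {
    rel <- (spikes - ev) * 1000
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel) > 0) {
      idx <- findInterval(rel, edges)
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  structure(
    list(counts = counts, bin_starts = edges[-length(edges)],
         bin_width = bin_width, window = window, n_events = length(events),
         baseline_window = baseline_window),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d bins of %g ms over [%g, %g] ms, %d events, %d spikes\n",
              length(x$counts), x$bin_width, x$window[1], x$window[2],
              x$n_events, sum(x$counts)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.peth <- function(x, ...) {
  tibble(time_ms = x$bin_starts, count = x$counts,
         rate_hz = x$counts / x$n_events / (x$bin_width / 1000))
}

#' Baseline confidence limits for a peri-event histogram
#'
#' Two-sided limits at the requested level, derived from the distribution of
#' per-bin counts in the baseline window (by default the second preceding each
#' event). `"percentile"` uses the empirical quantiles of the baseline counts;
#' `"normal"` uses `mean +/- z * SD`. With `method = "auto"` the percentile
#' rule is used when the baseline has at least 100 bins, otherwise the normal
#' approximation.
#'
#' @param peth A [build_peth()] object.
#' @param level Confidence level in percent (default 99).
#' @param method `"auto"`, `"percentile"` or `"normal"`.
#' @return A `baseline_limits` list: `baseline_mean`, `upper`, `lower`,
#'   `level`, `method`, `n_baseline_bins`.
#' @export
baseline_limits <- function(peth, level = 99, method = c("auto", "percentile", "normal")) {
  method <- match.arg(method)
  base <- peth$counts[peth$bin_starts >= peth$baseline_window[1] &
                        peth$bin_starts < peth$baseline_window[2]]
  if (length(base) == 0) abort("Baseline window contains no bins.")
  if (method == "auto") method <- if (length(base) >= 100) "percentile" else "normal"
  m <- mean(base)
  tail_p <- (1 - level / 100) / 2
  if (method == "percentile") {
    lims <- unname(quantile(base, c(tail_p, 1 - tail_p), type = 1))
  } else {
    z <- qnorm(1 - tail_p)
    lims <- m + c(-1, 1) * z * sd(base)
    if (is.na(lims[1])) lims <- c(m, m)  # single baseline bin
  }
  structure(
    list(baseline_mean = m, lower = lims[1], upper = lims[2],
         level = level, method = method, n_baseline_bins = length(base)),
    class = "baseline_limits"
  )
}

#' Classify a cell's responsiveness and latency
#'
#' A cell responds when at least `min_run` consecutive bins inside the response
#' window fall outside the baseline confidence limits, in either direction
#' (excitation above the upper limit, suppression below the lower). The
#' latency is the left edge of the first bin of the first qualifying run. Cells
#' with near-zero baseline cannot express a detectable suppression and are
#' flagged `indeterminate` when no excitation is found.
#'
#' @param peth A [build_peth()] object.
#' @param limits Optional [baseline_limits()]; computed at 99% by default.
#' @param response_window Window (ms) searched for responses; must lie within
#'   the PETH window. A run starting exactly at the window start is valid;
#'   runs extending past the end are truncated.
#' @param min_run Minimum number of consecutive significant bins.
#' @return A one-row tibble: `responsive`, `latency_ms`, `direction`
#'   (`"excitation"`/`"suppression"`/`NA`), `indeterminate`.
#' @export
classify_response <- function(peth, limits = NULL, response_window = c(5, 300),
                              min_run = 1) {
  limits <- limits %||% baseline_limits(peth)
  if (response_window[1] < peth$window[1] || response_window[2] > peth$window[2]) {
    abort("`response_window` must lie within the PETH window.")
  }
  sel <- peth$bin_starts >= response_window[1] & peth$bin_starts < response_window[2]
  x <- peth$counts[sel]
  starts <- peth$bin_starts[sel]
  state <- ifelse(x > limits$upper, 1L, ifelse(x < limits$lower, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  hit <- which(r$values != 0 & r$lengths >= min_run)
  if (length(hit) == 0) {
    near_zero <- limits$lower <= 0 && limits$baseline_mean < 0.02
    return(tibble(responsive = FALSE, latency_ms = NA_real_,
                  direction = NA_character_, indeterminate = near_zero))
  }
  first <- hit[1]
  tibble(
    responsive = TRUE,
    latency_ms = starts[begs[first]],
    direction = if (r$values[first] > 0) "excitation" else "suppression",
    indeterminate = FALSE
  )
}

#' Label a responsive cell with its response archetype
#'
#' The sequence of signed excursions outside the confidence limits within the
#' response window is collapsed to a sign string and matched against a fixed
#' rule tree: `+` alone gives `short_excitation`; a `+,-,+` prefix gives
#' `excitation_pause_rebound`; a leading `-` followed by an excitation starting
#' in 100-300 ms gives `pause_late_excitation`; `-` only gives `pause_only`.
#' Extra excursions beyond the first match are ignored (first-matching rule); a
#' leading suppression with an early re-excitation is labelled
#' `pause_late_excitation` with a message.
#'
#' @inheritParams classify_response
#' @return A character label, or `NA_character_` for non-responsive cells.
#' @export
classify_response_type <- function(peth, limits = NULL,
                                   response_window = c(5, 300), min_run = 1) {
  limits <- limits %||% baseline_limits(peth)
  prof <- classify_response(peth, limits, response_window, min_run)
  if (!prof$responsive) return(NA_character_)
  sel <- peth$bin_starts >= response_window[1] & peth$bin_starts < response_window[2]
  x <- peth$counts[sel]
  starts <- peth$bin_starts[sel]
  state <- ifelse(x > limits$upper, 1L, ifelse(x < limits$lower, -1L, 0L))
  r <- rle(state)
  keep <- r$values != 0 & r$lengths >= min_run
  signs <- r$values[keep]
  onsets <- starts[(cumsum(r$lengths) - r$lengths + 1)[keep]]
  if (signs[1] > 0) {
    if (length(signs) >= 3 && signs[2] < 0 && signs[3] > 0) {
      return("excitation_pause_rebound")
    }
    return("short_excitation")
  }
  pos <- which(signs > 0)
  if (length(pos) == 0) return("pause_only")
  if (any(onsets[pos] >= 100)) return("pause_late_excitation")
  inform("Suppression followed by an early re-excitation; labelled pause_late_excitation by first-matching rule.")
  "pause_late_excitation"
}

#' Response profiles for every cell of a spike table
#'
#' Convenience wrapper running [build_peth()], [baseline_limits()],
#' [classify_response()] and [classify_response_type()] per cell.
#'
#' @param spikes A spike table (`cell_id`, `time_s`, optionally `region`).
#' @param events Stimulus times, s.
#' @inheritParams classify_response
#' @param window,bin_width,baseline_window Passed to [build_peth()].
#' @param level,method Passed to [baseline_limits()].
#' @return A tibble with one row per cell: `cell_id`, `region`, `responsive`,
#'   `latency_ms`, `direction`, `response_type`, `indeterminate`.
#' @export
response_profiles <- function(spikes, events, window = c(-1000, 300),
                              bin_width = 1, baseline_window = c(-1000, 0),
                              response_window = c(5, 300), min_run = 1,
                              level = 99, method = "auto") {
  assert_spike_table(spikes)
  region <- if ("region" %in% names(spikes)) spikes$region else NA_character_
  spikes |>
    mutate(.region = region) |>
    group_by(.data$cell_id) |>
    group_modify(function(d, key) {
      p <- build_peth(d$time_s, events, window, bin_width, baseline_window)
      lim <- baseline_limits(p, level = level, method = method)
      prof <- classify_response(p, lim, response_window, min_run)
      prof$response_type <- if (prof$responsive) {
        classify_response_type(p, lim, response_window, min_run)
      } else NA_character_
      prof$region <- d$.region[1]
      prof
    }) |>
    ungroup() |>
    select("cell_id", "region", "responsive", "latency_ms", "direction",
           "response_type", "indeterminate")
}

#' Summarise response latencies across cells
#'
#' @param profiles A tibble of response profiles (from [response_profiles()]
#'   or assembled by hand) with at least `responsive` and `latency_ms`;
#'   summaries are per `region` when present.
#' @param max_latency_ms Optional restriction of the histogram/median to
#'   latencies below this value (e.g. 60 or 30 ms views).
#' @return A list with `summary` (per-region tibble: `n`, `n_responsive`,
#'   `responsive_pct`, `median_latency_ms`) and `histogram` (per-region counts
#'   at 1-ms resolution; empty when no cell is responsive).
#' @export
latency_summary <- function(profiles, max_latency_ms = NULL) {
  if (!"region" %in% names(profiles)) profiles$region <- "all"
  lat <- profiles |>
    filter(.data$responsive, !is.na(.data$latency_ms))
  if (!is.null(max_latency_ms)) lat <- filter(lat, .data$latency_ms < max_latency_ms)
  summary <- profiles |>
    group_by(.data$region) |>
    summarise(n = dplyr::n(), n_responsive = sum(.data$responsive),
              responsive_pct = 100 * sum(.data$responsive) / dplyr::n(),
              .groups = "drop") |>
    left_join(
      lat |> group_by(.data$region) |>
        summarise(median_latency_ms = median(.data$latency_ms), .groups = "drop"),
      by = "region"
    )
  histogram <- if (nrow(lat) == 0) {
    tibble(region = character(), latency_ms = numeric(), n = integer())
  } else {
    lat |>
      mutate(latency_ms = floor(.data$latency_ms)) |>
      count(.data$region, .data$latency_ms, name = "n")
  }
  list(summary = summary, histogram = histogram)
}
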