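#' Firing rates during task execution
#'
#' Each trial's running period is divided into non-overlapping 250-ms windows;
#' the rate is the spike count divided by 0.25 s, then smoothed within trial by
#' a Gaussian kernel (SD 750 ms, truncated at 3 SD and renormalised at trial
#' edges). Windows never straddle trials and a trailing partial window is
#' dropped; inter-trial spikes are excluded. Before smoothing the rates
#' conserve the in-trial spike count exactly: `sum(rate) * 0.25 = count`.
#'
#' @param spikes A spike table, or a numeric vector of spike times for one
#'   cell.
#' @param trials Tibble with `trial_id`, `start_s`, `end_s` running periods.
#' @param window_s Rate window, s.
#' @param smooth_sd_s Gaussian smoothing SD, s. Use 0 to skip smoothing.
#' @return A tibble: `cell_id`, `trial_id`, `t_mid`, `rate_raw`, `rate`.
#' @export
execution_rates <- function(spikes, trials, window_s = 0.25,
                            smooth_sd_s = 0.75) {
  if (is.numeric(spikes)) spikes <- tibble(cell_id = "cell", time_s = spikes)
  assert_spike_table(spikes)
  if (!all(c("trial_id", "start_s", "end_s") %in% names(trials))) {
    abort("`trials` must have trial_id, start_s, end_s.")
  }
  check_positive(window_s, "window_s")
  kern_half <- if (smooth_sd_s > 0) ceiling(3 * smooth_sd_s / window_s) else 0L
  kern <- if (kern_half > 0) dnorm(seq(-kern_half, kern_half) * window_s, sd = smooth_sd_s) else 1
  out <- tidyr::expand_grid(cell_id = unique(spikes$cell_id),
                            trial_id = trials$trial_id) |>
    purrr::pmap(function(cell_id, trial_id) {
      tr <- trials[trials$trial_id == trial_id, ]
      n_win <- floor((tr$end_s - tr$start_s) / window_s + 1e-9)
      if (n_win < 1) return(NULL)
      edges <- tr$start_s + window_s * (0:n_win)
      st <- spikes$time_s[spikes$cell_id == cell_id]
      st <- st[st >= edges[1] & st < edges[n_win + 1]]
      counts <- tabulate(findInterval(st, edges), nbins = n_win)
      raw <- counts / window_s
      sm <- if (kern_half > 0) {
        num <- as.numeric(stats::filter(raw, kern, sides = 2))
        den <- as.numeric(stats::filter(rep(1, n_win), kern, sides = 2))
        miss <- is.na(num)
        if (any(miss)) {  # renormalise truncated windows at trial edges
          for (i in which(miss)) {
            lo <- max(1, i - kern_half); hi <- min(n_win, i + kern_half)
            kk <- kern[(lo - i + kern_half + 1):(hi - i + kern_half + 1)]
            num[i] <- sum(raw[lo:hi] * kk); den[i] <- sum(kk)
          }
        }
        num / den
      } else raw
      tibble(cell_id = cell_id, trial_id = trial_id,
             t_mid = edges[-length(edges)] + window_s / 2,
             rate_raw = raw, rate = sm)
    }) |>
    dplyr::bind_rows()
  out
}

#' Correlate spiking activity with a kinematic trace
#'
#' The kinematic trace is averaged within each 250-ms rate window and one
#' Pearson coefficient per cell is computed across all windows of all trials.
#'
#' @param rates Output of [execution_rates()].
#' @param trace Tibble with `time_s` and `position` (e.g.
#'   [generate_forelimb_trace()]).
#' @param use `"rate"` (smoothed) or `"rate_raw"`.
#' @return A tibble: `cell_id`, `r`, `n_windows`.
#' @export
spike_position_correlation <- function(rates, trace, use = c("rate", "rate_raw")) {
  use <- match.arg(use)
  if (!all(c("time_s", "position") %in% names(trace))) {
    abort("`trace` must have time_s and position.")
  }
  win <- sort(unique(rates$t_mid))
  if (length(win) < 2) abort("Need at least two rate windows.")
  half <- min(diff(win)) / 2
  pos_at <- vapply(win, function(t0) {
    mean(trace$position[trace$time_s >= t0 - half & trace$time_s < t0 + half])
  }, numeric(1))
  lookup <- setNames(pos_at, format(win, digits = 12))
  rates |>
    mutate(pos = unname(lookup[format(.data$t_mid, digits = 12)])) |>
    group_by(.data$cell_id) |>
    summarise(
      r = if (sum(complete.cases(.data[[use]], .data$pos)) > 2 &&
              sd(.data[[use]], na.rm = TRUE) > 0 && sd(.data$pos, na.rm = TRUE) > 0) {
        cor(.data[[use]], .data$pos, use = "complete.obs")
      } else NA_real_,
      n_windows = sum(!is.na(.data$pos)),
      .groups = "drop"
    )
}

#' Spike-train autocorrelogram and rhythmicity
#'
#' Counts of spike-time differences in lag bins over `[-lag_max, +lag_max]`
#' (symmetric by construction, zero-lag self-pairs excluded). The modulation
#' frequency is `1 / lag` of the first non-central peak of the smoothed
#' positive-lag autocorrelogram, and the modulation index is
#' `(peak - trough) / (peak + trough)` using the trough preceding that peak.
#' The modulation index is a summary invented for this package (autocorrelogram
#' rhythmicity is usually assessed visually) and is flagged as such in outputs.
#'
#' @param spike_times Numeric vector of spike times, s.
#' @param lag_max_ms Maximum lag, ms.
#' @param bin_ms Lag bin width, ms.
#' @param smooth_bins Width (bins) of the moving average applied before peak
#'   picking.
#' @return A `rhythmicity` object: `autocorrelogram` tibble (`lag_ms`,
#'   `count`), `modulation_frequency_hz`, `modulation_index`, `is_package_metric`.
#' @export
rhythmicity <- function(spike_times, lag_max_ms = 1000, bin_ms = 10,
                        smooth_bins = 3) {
  check_positive(lag_max_ms, "lag_max_ms")
  check_positive(bin_ms, "bin_ms")
  st <- sort(spike_times)
  n <- length(st)
  if (n < 2) abort("Need at least two spikes.")
  lag_max <- lag_max_ms / 1000
  diffs <- numeric(0)
  j <- 1L
  for (i in seq_len(n - 1)) {
    k <- i + 1L
    while (k <= n && st[k] - st[i] <= lag_max) k <- k + 1L
    if (k > i + 1L) diffs <- c(diffs, st[(i + 1L):(k - 1L)] - st[i])
  }
  n_bins <- ceiling(lag_max_ms / bin_ms)
  pos_counts <- tabulate(pmin(floor(diffs * 1000 / bin_ms) + 1L, n_bins), nbins = n_bins)
  lags <- (seq_len(n_bins) - 0.5) * bin_ms
  acg <- tibble(lag_ms = c(-rev(lags), lags),
                count = c(rev(pos_counts), pos_counts))
  sm <- as.numeric(stats::filter(pos_counts, rep(1 / smooth_bins, smooth_bins), sides = 2))
  sm[is.na(sm)] <- pos_counts[is.na(sm)]
  # skip the central peak: take the global trough over the first half of the
  # lag range, then the maximum beyond it as the first rhythmic peak
  freq <- NA_real_; index <- 0
  if (n_bins >= 5) {
    w0 <- max(2L, smooth_bins)
    # first local minimum of the smoothed curve = end of the central peak
    is_local_min <- vapply(seq_len(n_bins), function(i) {
      sm[i] == min(sm[max(1, i - w0):min(n_bins, i + w0)])
    }, logical(1))
    trough <- which(is_local_min)[1]
    if (is.na(trough)) trough <- which.min(sm[seq_len(max(2L, floor(n_bins / 2)))])
    if (trough < n_bins) {
      tr_val <- sm[trough]
      gmax <- max(sm[(trough + 1):n_bins])
      w <- max(2L, smooth_bins)
      is_local_max <- vapply(seq_len(n_bins), function(i) {
        sm[i] == max(sm[max(1, i - w):min(n_bins, i + w)])
      }, logical(1))
      cand <- which(is_local_max)
      cand <- cand[cand > trough & sm[cand] >= (gmax + tr_val) / 2]
      pk <- if (length(cand) > 0) cand[1] else trough + which.max(sm[(trough + 1):n_bins])
      lag_pk <- lags[pk]
      if (pk > 1 && pk < n_bins) {
        # parabolic interpolation of the peak against lag-bin quantisation
        den <- sm[pk - 1] - 2 * sm[pk] + sm[pk + 1]
        if (is.finite(den) && den < 0) {
          lag_pk <- lag_pk + bin_ms * 0.5 * (sm[pk - 1] - sm[pk + 1]) / den
        }
      }
      freq <- 1000 / lag_pk
      pk_val <- sm[pk]
      if (pk_val + tr_val > 0) index <- (pk_val - tr_val) / (pk_val + tr_val)
    }
  }
  structure(
    list(autocorrelogram = acg, modulation_frequency_hz = freq,
         modulation_index = max(index, 0), is_package_metric = TRUE),
    class = "rhythmicity"
  )
}

#' @export
print.rhythmicity <- function(x, ...) {
  cat(sprintf("<rhythmicity> modulation %.2f Hz, index %.3f (package-defined index)\n",
              x$modulation_frequency_hz, x$modulation_index))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rhythmicity <- function(x, ...) x$autocorrelogram

#' @exportS3Method generics::glance
glance.rhythmicity <- function(x, ...) {
  tibble(modulation_frequency_hz = x$modulation_frequency_hz,
         modulation_index = x$modulation_index,
         is_package_metric = x$is_package_metric)
}
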