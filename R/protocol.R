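#' Describe a rhythmic stimulation protocol
#'
#' A stimulation session is organised as trains of brief stimuli delivered at a
#' fixed within-train rate, with trains separated by random intervals. The
#' defaults describe 50 trains of 5 stimuli at 3.3 Hz (5-ms stimuli) separated
#' by 5-10 s gaps, i.e. a rhythm matching the forelimb step cycle of a rat
#' running at about 30 cm/s.
#'
#' @param n_trains Number of stimulation trains.
#' @param n_stimuli Number of stimuli per train.
#' @param train_rate Within-train stimulation rate in Hz.
#' @param stimulus_duration_ms Duration of each stimulus in ms (metadata only;
#'   stimuli are treated as instantaneous events at their onsets).
#' @param inter_train_interval Length-2 numeric, uniform range (s) of the gap
#'   between the last stimulus of one train and the onset of the next.
#' @param first_onset Time (s) of the first train onset.
#'
#' @return A `stim_protocol` object (a list). Event times are filled in by
#'   [generate_protocol()].
#' @seealso [generate_protocol()]
#' @export
#' @examples
#' generate_protocol(stim_protocol(n_trains = 2), seed = 1)
stim_protocol <- function(n_trains = 50, n_stimuli = 5, train_rate = 3.3,
                          stimulus_duration_ms = 5,
                          inter_train_interval = c(5, 10),
                          first_onset = 5) {
  check_positive(n_trains, "n_trains")
  check_positive(n_stimuli, "n_stimuli")
  check_positive(train_rate, "train_rate")
  check_positive(stimulus_duration_ms, "stimulus_duration_ms")
  if (length(inter_train_interval) != 2 || diff(inter_train_interval) < 0 ||
      any(inter_train_interval < 0)) {
    abort("`inter_train_interval` must be an increasing non-negative range (min_s, max_s).")
  }
  structure(
    list(
      n_trains = as.integer(n_trains),
      n_stimuli = as.integer(n_stimuli),
      train_rate = train_rate,
      stimulus_duration_ms = stimulus_duration_ms,
      inter_train_interval = inter_train_interval,
      first_onset = first_onset,
      train_onsets = NULL,
      events = NULL
    ),
    class = "stim_protocol"
  )
}

#' Draw concrete event times for a stimulation protocol
#'
#' Train onsets are laid out sequentially: each gap between the end of one
#' train and the next onset is drawn uniformly from the protocol's inter-train
#' interval. Within a train, stimulus `k` (1-based) occurs at
#' `onset + (k - 1) / train_rate`.
#'
#' @param spec A [stim_protocol()] object.
#' @param seed Integer seed; the realised protocol is reproducible per seed.
#'
#' @return The protocol with `train_onsets` (numeric, s) and `events`, a tibble
#'   with columns `train_id`, `stim_index`, `time_s`.
#' @export
generate_protocol <- function(spec, seed = 1L) {
  if (!inherits(spec, "stim_protocol")) abort("`spec` must be a `stim_protocol`.")
  train_span <- (spec$n_stimuli - 1) / spec$train_rate
  gaps <- withr_seed(seed, runif(spec$n_trains - 1,
                                 spec$inter_train_interval[1],
                                 spec$inter_train_interval[2]))
  onsets <- spec$first_onset + c(0, cumsum(train_span + gaps))
  events <- tidyr::expand_grid(
    train_id = seq_len(spec$n_trains),
    stim_index = seq_len(spec$n_stimuli)
  ) |>
    mutate(time_s = onsets[.data$train_id] + (.data$stim_index - 1) / spec$train_rate)
  spec$train_onsets <- onsets
  spec$events <- events
  spec$seed <- as.integer(seed)
  spec
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d trains x %d stimuli at %.2f Hz\n",
              x$n_trains, x$n_stimuli, x$train_rate))
  if (!is.null(x$events)) {
    cat(sprintf("  %d stimulus events, onsets %.2f-%.2f s\n",
                nrow(x$events), min(x$train_onsets), max(x$train_onsets)))
  } else {
    cat("  event times not yet generated; see generate_protocol()\n")
  }
  invisible(x)
}

#' Session duration covering all protocol events
#'
#' @param protocol A realised [stim_protocol()].
#' @param pad_s Seconds appended after the last stimulus.
#' @return Duration in s.
#' @export
protocol_duration <- function(protocol, pad_s = 2) {
  if (is.null(protocol$events)) abort("Protocol has no event times; call generate_protocol().")
  max(protocol$events$time_s) + pad_s
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are reproducible and side-effect free.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
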