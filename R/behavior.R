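# accept a behavior_session or a long trace tibble
as_behavior_trace <- function(x, arg = "trials") {
  if (inherits(x, "behavior_session")) x <- x$trace
  if (!is.data.frame(x) ||
      !all(c("trial_id", "time_s", "position_cm") %in% names(x))) {
    abort(sprintf("`%s` must be a behavior_session or a tibble with trial_id, time_s, position_cm.", arg))
  }
  x
}

#' Smooth a position trace with a centred moving average
#'
#' Windows are truncated at the trace edges (the average runs over the samples
#' available), so the output has the same length as the input and constant or
#' affine stretches are preserved in the interior. The 400-ms default matches
#' the average duration of a step cycle.
#'
#' @param position Numeric position vector, evenly sampled.
#' @param window_ms Averaging window, ms.
#' @param sample_rate Sampling rate, Hz.
#' @return Smoothed numeric vector, same length.
#' @export
smooth_position <- function(position, window_ms = 400, sample_rate = 100) {
  check_positive(window_ms, "window_ms")
  check_positive(sample_rate, "sample_rate")
  n <- length(position)
  half <- floor(window_ms / 1000 * sample_rate / 2)
  if (half == 0 || n == 0) return(position)
  cs <- cumsum(c(0, position))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect the goal-area entrance time and trial correctness
#'
#' The entrance time is the first sample at which the position falls below the
#' goal-area boundary after the animal has left the goal area (trials start
#' near the front wall, inside the goal area, and are carried out of it by the
#' belt). A trial is correct when the entrance occurs at or after the goal
#' time. Trials that never re-enter are flagged with `NA` entrance.
#'
#' @param trials A `behavior_session` or long trace tibble (`trial_id`,
#'   `time_s`, `position_cm`).
#' @param goal_area Goal-area depth from the front wall, cm.
#' @param goal_time Goal time, s.
#' @return A tibble: `trial_id`, `entrance_time`, `correct` (`NA` entrance
#'   gives `correct = NA`).
#' @export
detect_entrance <- function(trials, goal_area = 10, goal_time = 7) {
  trace <- as_behavior_trace(trials)
  trace |>
    group_by(.data$trial_id) |>
    group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_s)
      outside <- which(d$position_cm >= goal_area)
      if (length(outside) == 0) {
        return(tibble(entrance_time = NA_real_, correct = NA))
      }
      after <- which(d$position_cm < goal_area & seq_len(nrow(d)) > outside[1])
      if (length(after) == 0) {
        return(tibble(entrance_time = NA_real_, correct = NA))
      }
      te <- d$time_s[after[1]]
      tibble(entrance_time = te, correct = te >= goal_time)
    }) |>
    ungroup()
}

#' Session-level performance summary
#'
#' @param trials A `behavior_session`, a long trace tibble, or a per-trial
#'   tibble already holding `entrance_time` and `correct` (e.g. from
#'   [detect_entrance()]).
#' @param window_trials Number of most recent trials over which the criterion
#'   is evaluated.
#' @param criterion Percent-correct criterion over the last `window_trials`.
#' @param goal_area,goal_time Passed to [detect_entrance()] when entrances are
#'   not supplied.
#' @return A one-row tibble: `n_trials`, `percent_correct`,
#'   `percent_correct_last`, `criterion_met`, `median_entrance_time`,
#'   `entrance_iqr`.
#' @export
session_summary <- function(trials, window_trials = 40, criterion = 72.5,
                            goal_area = 10, goal_time = 7) {
  ent <- if (is.data.frame(trials) && all(c("entrance_time", "correct") %in% names(trials))) {
    trials
  } else {
    detect_entrance(trials, goal_area = goal_area, goal_time = goal_time)
  }
  if (nrow(ent) == 0) abort("No trials to summarise.")
  ent <- dplyr::arrange(ent, .data$trial_id)
  last <- tail(ent, window_trials)
  pc_last <- 100 * mean(last$correct, na.rm = TRUE)
  tibble(
    n_trials = nrow(ent),
    percent_correct = 100 * mean(ent$correct, na.rm = TRUE),
    percent_correct_last = pc_last,
    criterion_met = pc_last >= criterion,
    median_entrance_time = median(ent$entrance_time, na.rm = TRUE),
    entrance_iqr = stats::IQR(ent$entrance_time, na.rm = TRUE)
  )
}

# locomotor (running) speed in cm/s from a position trace:
# belt speed minus the centred derivative of the (smoothed) position.
# Holding position on a 22 cm/s belt means running at 22 cm/s.
ground_speed <- function(position, sample_rate, treadmill_speed,
                         smooth_ms = 400) {
  p <- smooth_position(position, smooth_ms, sample_rate)
  n <- length(p)
  if (n < 3) return(rep(treadmill_speed, n))
  dp <- numeric(n)
  dp[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / 2 * sample_rate
  dp[1] <- (p[2] - p[1]) * sample_rate
  dp[n] <- (p[n] - p[n - 1]) * sample_rate
  treadmill_speed - dp
}

#' Pairwise trajectory stereotypy of a session
#'
#' Position (or speed) trajectories are aligned to their entrance times and
#' Pearson correlations are computed for all trial pairs. For position the
#' common pre-entrance overlap across included trials is used (trials with less
#' than `min_pre_s` before their entrance are excluded); for speed the analysis
#' is restricted to a fixed window before entrance (2.5 s by default). The
#' stereotypy index is the median of the pairwise coefficients.
#'
#' @param trials A `behavior_session` or long trace tibble.
#' @param signal `"position"` or `"speed"`.
#' @param goal_area,goal_time Entrance-detection parameters.
#' @param sample_rate Sampling rate, Hz.
#' @param treadmill_speed Belt speed, cm/s (used for the speed signal).
#' @param speed_window_s Pre-entrance window for the speed signal, s.
#' @param min_pre_s Minimum pre-entrance span for a trial to be included.
#' @param index `"median"` (default) or `"mean"` aggregation of the pairwise
#'   coefficients.
#' @return A `stereotypy` object: `matrix` (trials x trials, unit diagonal),
#'   `pairs` tibble, `index`, `signal`, `trial_ids`.
#' @export
stereotypy_index <- function(trials, signal = c("position", "speed"),
                             goal_area = 10, goal_time = 7, sample_rate = 100,
                             treadmill_speed = 22, speed_window_s = 2.5,
                             min_pre_s = 1, index = c("median", "mean")) {
  signal <- match.arg(signal)
  index_fun <- switch(match.arg(index), median = median, mean = mean)
  trace <- as_behavior_trace(trials)
  ent <- detect_entrance(trace, goal_area = goal_area, goal_time = goal_time)
  ok <- ent |> filter(!is.na(.data$entrance_time), .data$entrance_time >= min_pre_s)
  if (nrow(ok) < 2) abort("Stereotypy needs at least 2 usable trials.")
  pre_span <- if (signal == "speed") speed_window_s else min(ok$entrance_time)
  n_samp <- floor(pre_span * sample_rate)
  aligned <- purrr::map(seq_len(nrow(ok)), function(i) {
    d <- trace |> filter(.data$trial_id == ok$trial_id[i]) |>
      dplyr::arrange(.data$time_s)
    te <- ok$entrance_time[i]
    sel <- d$time_s > te - pre_span - 1e-9 & d$time_s <= te + 1e-9
    y <- d$position_cm[sel]
    y <- tail(y, n_samp)
    if (signal == "speed") {
      tail(ground_speed(d$position_cm, sample_rate, treadmill_speed)[sel], n_samp)
    } else y
  })
  len <- min(lengths(aligned))
  m <- vapply(aligned, function(y) tail(y, len), numeric(len))
  cm <- suppressWarnings(cor(m))
  cm[is.na(cm)] <- 1  # zero-variance pairs: identical constant segments
  diag(cm) <- 1
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  structure(
    list(matrix = cm,
         pairs = tibble(trial_a = ok$trial_id[pairs[, 1]],
                        trial_b = ok$trial_id[pairs[, 2]],
                        r = cm[pairs]),
         index = index_fun(cm[upper.tri(cm)]),
         signal = signal, trial_ids = ok$trial_id),
    class = "stereotypy"
  )
}

#' @export
print.stereotypy <- function(x, ...) {
  cat(sprintf("<stereotypy> %s index = %.3f over %d trials (%d pairs)\n",
              x$signal, x$index, length(x$trial_ids), nrow(x$pairs)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stereotypy <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.stereotypy <- function(x, ...) {
  tibble(signal = x$signal, index = x$index,
         n_trials = length(x$trial_ids), n_pairs = nrow(x$pairs))
}

#' Segment a trial into Front-Back-Front phases
#'
#' Phases partition the interval from treadmill onset to the entrance time:
#' front-to-back runs until the first entry into the rear zone, holding lasts
#' until the last exit from the rear zone preceding the entrance, and
#' back-to-front covers the final sprint. The three durations sum to the
#' entrance time exactly. Trials that never reach the rear zone are flagged.
#'
#' @param trials A `behavior_session` or long trace tibble.
#' @param rear_zone Depth of the rear zone, cm from the rear wall.
#' @param goal_area,goal_time Entrance-detection parameters.
#' @param belt_length Belt length, cm.
#' @return A tibble per trial: `front_to_back`, `holding`, `back_to_front`,
#'   `entrance_time`, `reached_rear`.
#' @export
segment_phases <- function(trials, rear_zone = 15, goal_area = 10,
                           goal_time = 7, belt_length = 80) {
  trace <- as_behavior_trace(trials)
  ent <- detect_entrance(trace, goal_area = goal_area, goal_time = goal_time)
  rear_at <- belt_length - rear_zone
  trace |>
    group_by(.data$trial_id) |>
    group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_s)
      te <- ent$entrance_time[ent$trial_id == key$trial_id]
      if (is.na(te)) {
        return(tibble(front_to_back = NA_real_, holding = NA_real_,
                      back_to_front = NA_real_, entrance_time = NA_real_,
                      reached_rear = NA))
      }
      pre <- d[d$time_s <= te, ]
      in_rear <- pre$position_cm >= rear_at
      if (!any(in_rear)) {
        return(tibble(front_to_back = NA_real_, holding = NA_real_,
                      back_to_front = NA_real_, entrance_time = te,
                      reached_rear = FALSE))
      }
      t_enter <- pre$time_s[which(in_rear)[1]]
      t_exit <- pre$time_s[max(which(in_rear))]
      tibble(front_to_back = t_enter, holding = t_exit - t_enter,
             back_to_front = te - t_exit, entrance_time = te,
             reached_rear = TRUE)
    }) |>
    ungroup()
}

#' Speed statistics of free-running traces
#'
#' Computes the locomotor speed (belt speed minus the derivative of the
#' smoothed position, so that holding position on the moving belt counts as
#' running at belt speed), a normalised speed-occupancy histogram, the maximum
#' speed, and the distance covered (integral of |speed|).
#'
#' @param traces A single trace tibble (`time_s`, `position_cm`) or a list of
#'   them (e.g. the `punishment` traces of a [generate_behavior_session()]).
#' @param treadmill_speed Belt speed, cm/s.
#' @param sample_rate Sampling rate, Hz.
#' @param speed_breaks Histogram bin edges, cm/s.
#' @param smooth_ms Position smoothing window, ms.
#' @return A list: `occupancy` tibble (`speed_lo`, `speed_hi`, `proportion`,
#'   summing to 1), `max_speed`, `distance_cm`, `duration_s`.
#' @export
speed_statistics <- function(traces, treadmill_speed = 22, sample_rate = 100,
                             speed_breaks = seq(0, 80, by = 5),
                             smooth_ms = 400) {
  if (is.data.frame(traces)) traces <- list(traces)
  traces <- purrr::compact(traces)
  if (length(traces) == 0 || all(vapply(traces, nrow, 1L) < 2)) {
    abort("Speed statistics need at least one trace with two or more samples.")
  }
  speeds <- unlist(lapply(traces, function(tr) {
    ground_speed(tr$position_cm, sample_rate, treadmill_speed, smooth_ms)
  }))
  dt <- 1 / sample_rate
  br <- unique(c(speed_breaks, max(speed_breaks, max(speeds) + 1e-9)))
  h <- graphics::hist(pmin(pmax(speeds, min(br)), max(br) - 1e-12),
                      breaks = br, plot = FALSE)
  occupancy <- tibble(speed_lo = head(h$breaks, -1), speed_hi = h$breaks[-1],
                      proportion = h$counts / sum(h$counts))
  list(occupancy = occupancy,
       max_speed = max(speeds),
       distance_cm = sum(abs(speeds)) * dt,
       duration_s = length(speeds) * dt)
}
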