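#' Specify a synthetic treadmill session
#'
#' Trials follow the stereotyped Front-Back-Front strategy on a motorised
#' treadmill: the animal starts near the front wall, is passively carried to
#' the rear at belt speed, holds its position at the rear by running at belt
#' speed for a drawn holding duration, then accelerates across the belt and
#' enters the goal area at the front. The entrance time is the first crossing
#' into the goal area; a trial is correct when the entrance occurs at or after
#' the goal time. Trial-to-trial variability enters through the holding
#' duration and the acceleration onset, the phases that carry the timing of the
#' sequence; belt kinematics are deterministic.
#'
#' @param n_trials Number of trials.
#' @param goal_time Minimum entrance time for a correct trial, s.
#' @param treadmill_speed Belt speed, cm/s.
#' @param belt_length Walkable belt length, cm (front wall at 0).
#' @param goal_area Goal-area depth from the front wall, cm.
#' @param holding_duration Length-2 numeric `(mean_s, sd_s)` of the holding
#'   phase at the rear.
#' @param timing_noise SD (s) of the acceleration-onset noise, added on top of
#'   the holding-duration draw.
#' @param sample_rate Position sampling rate, Hz.
#' @param start_position Position at treadmill onset, cm from the front wall.
#' @param rear_position Position held during the holding phase, cm.
#' @param run_speed Locomotor speed during the final acceleration, cm/s
#'   (must exceed `treadmill_speed` so the animal progresses toward the front).
#' @param position_noise SD (cm) of additive position measurement noise.
#' @param punishment_duration Length of the extra run following an incorrect
#'   trial, s.
#' @param seed Default seed used by [generate_behavior_session()].
#'
#' @return A `behavior_spec` object.
#' @export
behavior_spec <- function(n_trials = 100, goal_time = 7, treadmill_speed = 22,
                          belt_length = 80, goal_area = 10,
                          holding_duration = c(2.545, 0.25),
                          timing_noise = 0.15, sample_rate = 100,
                          start_position = 5, rear_position = 70,
                          run_speed = 52, position_noise = 0,
                          punishment_duration = 20, seed = 1L) {
  check_positive(n_trials, "n_trials")
  check_positive(sample_rate, "sample_rate")
  if (goal_area >= belt_length) abort("`goal_area` must be smaller than `belt_length`.")
  if (length(holding_duration) != 2 || holding_duration[1] < 0 || holding_duration[2] < 0) {
    abort("`holding_duration` must be (mean_s, sd_s) with a non-negative mean.")
  }
  if (run_speed <= treadmill_speed) abort("`run_speed` must exceed `treadmill_speed`.")
  if (rear_position <= goal_area || rear_position > belt_length) {
    abort("`rear_position` must lie between `goal_area` and `belt_length`.")
  }
  structure(
    list(n_trials = as.integer(n_trials), goal_time = goal_time,
         treadmill_speed = treadmill_speed, belt_length = belt_length,
         goal_area = goal_area, holding_duration = holding_duration,
         timing_noise = timing_noise, sample_rate = sample_rate,
         start_position = start_position, rear_position = rear_position,
         run_speed = run_speed, position_noise = position_noise,
         punishment_duration = punishment_duration, seed = as.integer(seed)),
    class = "behavior_spec"
  )
}

#' Closed-form entrance time of the kinematic template
#'
#' With zero noise a trial's entrance time decomposes exactly into the passive
#' front-to-back drift, the holding duration, and the back-to-front sprint to
#' the goal-area boundary.
#'
#' @param spec A [behavior_spec()].
#' @param holding_s Holding duration, s; defaults to the spec's mean.
#' @return Entrance time in s.
#' @export
template_entrance_time <- function(spec, holding_s = spec$holding_duration[1]) {
  drift <- (spec$rear_position - spec$start_position) / spec$treadmill_speed
  sprint <- (spec$rear_position - spec$goal_area) / (spec$run_speed - spec$treadmill_speed)
  drift + holding_s + sprint
}

# Piecewise position template for one trial, sampled at spec$sample_rate.
template_trace <- function(spec, holding_s, post_s = 0.5) {
  v <- spec$treadmill_speed
  dt <- 1 / spec$sample_rate
  t_drift <- (spec$rear_position - spec$start_position) / v
  sprint_rate <- spec$run_speed - v
  t_sprint_goal <- (spec$rear_position - spec$goal_area) / sprint_rate
  # run past the goal boundary down to the front resting position
  t_sprint_end <- (spec$rear_position - spec$start_position) / sprint_rate
  t_end <- t_drift + holding_s + t_sprint_end + post_s
  tt <- seq(0, t_end, by = dt)
  pos <- numeric(length(tt))
  phase1 <- tt < t_drift
  pos[phase1] <- spec$start_position + v * tt[phase1]
  phase2 <- tt >= t_drift & tt < t_drift + holding_s
  pos[phase2] <- spec$rear_position
  phase3 <- tt >= t_drift + holding_s
  pos[phase3] <- pmax(spec$start_position,
                      spec$rear_position - sprint_rate * (tt[phase3] - t_drift - holding_s))
  tibble(time_s = tt, position_cm = pmin(pmax(pos, 0), spec$belt_length))
}

#' Simulate a treadmill session of Front-Back-Front trials
#'
#' @param spec A [behavior_spec()].
#' @param seed Integer seed.
#' @return A `behavior_session` object: a list with `trace` (long tibble:
#'   `trial_id`, `time_s`, `position_cm`), `trials` (per-trial metadata with
#'   the generated holding duration, entrance time, and correctness, plus a
#'   `punishment` list-column of extra-run traces for incorrect trials) and the
#'   `spec`.
#' @export
generate_behavior_session <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "behavior_spec")) abort("`spec` must be a `behavior_spec`.")
  withr_seed(seed, {
    hold <- pmax(0, rnorm(spec$n_trials, spec$holding_duration[1], spec$holding_duration[2]) +
                   rnorm(spec$n_trials, 0, spec$timing_noise))
    traces <- lapply(seq_len(spec$n_trials), function(i) {
      tr <- template_trace(spec, hold[i])
      if (spec$position_noise > 0) {
        tr$position_cm <- pmin(pmax(tr$position_cm + rnorm(nrow(tr), 0, spec$position_noise), 0),
                               spec$belt_length)
      }
      tr$trial_id <- i
      tr
    })
    trace <- dplyr::bind_rows(traces)[, c("trial_id", "time_s", "position_cm")]
    entrance <- vapply(seq_len(spec$n_trials),
                       function(i) template_entrance_time(spec, hold[i]),
                       numeric(1))
    correct <- entrance >= spec$goal_time
    punishment <- lapply(seq_len(spec$n_trials), function(i) {
      if (correct[i]) NULL else generate_punishment_run(spec)
    })
    trials <- tibble(
      trial_id = seq_len(spec$n_trials),
      holding_s = hold,
      entrance_time = entrance,
      correct = correct,
      punishment = punishment
    )
    structure(list(trace = trace, trials = trials, spec = spec),
              class = "behavior_session")
  })
}

# Extra run after an incorrect trial: variable locomotor speed around belt
# speed, position integrated and reflected into the belt.
generate_punishment_run <- function(spec) {
  dt <- 1 / spec$sample_rate
  tt <- seq(0, spec$punishment_duration, by = dt)
  n <- length(tt)
  wob <- stats::filter(rnorm(n, 0, 4), rep(1 / 25, 25), circular = TRUE)
  speed <- pmax(0, spec$treadmill_speed + 8 * sin(2 * pi * tt / 6) + as.numeric(wob))
  pos <- spec$start_position + cumsum(c(0, (spec$treadmill_speed - speed[-1]) * dt))
  # reflect into [0, belt_length]
  period <- 2 * spec$belt_length
  pos <- pos %% period
  pos <- ifelse(pos > spec$belt_length, period - pos, pos)
  tibble(time_s = tt, position_cm = pos)
}

#' @export
print.behavior_session <- function(x, ...) {
  cat(sprintf("<behavior_session> %d trials, %.0f%% correct (goal time %.1f s)\n",
              nrow(x$trials), 100 * mean(x$trials$correct), x$spec$goal_time))
  invisible(x)
}

#' Simulate a forelimb kinematic trace
#'
#' A sinusoidal limb position at the stepping rate during running epochs (flat
#' elsewhere), plus optional white measurement noise. Used to probe
#' spike-kinematics correlation recovery.
#'
#' @param step_rate Stepping rate, Hz.
#' @param duration Session duration, s.
#' @param sample_rate Sampling rate, Hz.
#' @param amplitude Sinusoid amplitude (cm or arbitrary units).
#' @param offset Forward displacement of the limb while stepping; the trace
#'   oscillates around `offset` during running and rests at 0 otherwise, as a
#'   limb marker does when the animal lifts the paw into its stride.
#' @param noise_sd SD of additive white noise.
#' @param running Optional tibble with `start_s`, `end_s` running epochs; the
#'   trace is flat outside them. Default: running throughout.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A tibble with `time_s`, `position`.
#' @export
generate_forelimb_trace <- function(step_rate = 3.3, duration = 60,
                                    sample_rate = 100, amplitude = 1,
                                    offset = 1, noise_sd = 0, running = NULL,
                                    seed = 1L) {
  check_positive(step_rate, "step_rate")
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  tt <- seq(0, duration, by = 1 / sample_rate)
  pos <- offset + amplitude * sin(2 * pi * step_rate * tt)
  if (!is.null(running)) {
    on <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(running))) {
      on <- on | (tt >= running$start_s[i] & tt < running$end_s[i])
    }
    pos[!on] <- 0
  }
  if (noise_sd > 0) pos <- pos + withr_seed(seed, rnorm(length(tt), 0, noise_sd))
  tibble(time_s = tt, position = pos)
}
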