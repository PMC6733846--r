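test_that("position smoothing preserves constants, ramps and mass", {
  expect_equal(smooth_position(rep(4, 50)), rep(4, 50))
  ramp <- seq(0, 10, length.out = 200)
  sm <- smooth_position(ramp)
  inner <- 21:180
  expect_equal(sm[inner], ramp[inner], tolerance = 1e-12)
  # unit impulse spreads over at most 41 samples and conserves interior mass
  imp <- c(rep(0, 100), 1, rep(0, 100))
  smi <- smooth_position(imp)
  expect_lte(sum(smi > 0), 41)
  expect_equal(sum(smi), 1, tolerance = 1e-12)
})

test_that("entrance detection applies the goal rule exactly", {
  mk <- function(te) {
    tt <- seq(0, 10, by = 0.01)
    pos <- ifelse(tt < 0.5, 5, ifelse(tt < te, 40, 5))
    tibble::tibble(trial_id = 1, time_s = tt, position_cm = pos)
  }
  e1 <- detect_entrance(mk(7.5))
  expect_equal(e1$entrance_time, 7.5)
  expect_true(e1$correct)
  e2 <- detect_entrance(mk(6.9))
  expect_false(e2$correct)
  # perturbing positions strictly above the goal area never moves the entrance
  tr <- mk(7.5)
  tr$position_cm[tr$position_cm >= 10] <- tr$position_cm[tr$position_cm >= 10] +
    runif(sum(tr$position_cm >= 10), 0, 30)
  expect_equal(detect_entrance(tr)$entrance_time, 7.5)
  # a trial that never re-enters is flagged
  tr2 <- tibble::tibble(trial_id = 1, time_s = seq(0, 5, 0.01), position_cm = 50)
  expect_true(is.na(detect_entrance(tr2)$entrance_time))
})

test_that("session summaries implement the percent and criterion arithmetic", {
  ent <- tibble::tibble(trial_id = 1:60,
                        entrance_time = c(rep(8, 50), rep(6, 10)),
                        correct = c(rep(TRUE, 50), rep(FALSE, 10)))
  s <- session_summary(ent)
  expect_equal(s$percent_correct, 100 * 50 / 60)
  expect_equal(s$percent_correct_last, 100 * 30 / 40)
  expect_true(s$criterion_met)  # 75% >= 72.5%
  # failures in the window tip the criterion: 29/40 = 72.5% still passes,
  # 28/40 = 70% does not
  ent$correct[21] <- FALSE
  expect_true(session_summary(ent)$criterion_met)
  expect_equal(session_summary(ent)$percent_correct_last, 100 * 29 / 40)
  ent$correct[22] <- FALSE
  expect_false(session_summary(ent)$criterion_met)
  expect_error(session_summary(ent[0, ]), "No trials")
  all_ok <- dplyr::mutate(ent, correct = TRUE)
  expect_equal(session_summary(all_ok)$percent_correct, 100)
})

test_that("stereotypy counts pairs and decreases monotonically with timing noise", {
  ses <- generate_behavior_session(behavior_spec(n_trials = 10, seed = 1))
  st <- stereotypy_index(ses)
  expect_equal(nrow(st$pairs), choose(10, 2))
  expect_true(isSymmetric(st$matrix))
  expect_true(all(diag(st$matrix) == 1))
  # moderate noise range: the common pre-entrance overlap stays long, so the
  # index declines monotonically with timing noise
  idx <- sapply(c(0, 0.1, 0.2, 0.35, 0.5), function(noise) {
    bs <- behavior_spec(n_trials = 25, holding_duration = c(2.545, 0),
                        timing_noise = noise, seed = 6)
    stereotypy_index(generate_behavior_session(bs))$index
  })
  expect_equal(idx[1], 1)
  expect_true(all(diff(idx) < 0))
  expect_error(stereotypy_index(
    generate_behavior_session(behavior_spec(n_trials = 1, seed = 1))),
    "2 usable")
})

test_that("phase segmentation recovers the template and partitions the entrance time", {
  bs <- behavior_spec(n_trials = 40, seed = 7)
  ses <- generate_behavior_session(bs)
  ph <- segment_phases(ses)
  expect_equal(ph$front_to_back + ph$holding + ph$back_to_front,
               ph$entrance_time)
  # template recovery on a noiseless trial: drift to the rear-zone edge (65 cm)
  bs0 <- behavior_spec(n_trials = 1, holding_duration = c(2.5, 0),
                       timing_noise = 0, seed = 1)
  ph0 <- segment_phases(generate_behavior_session(bs0))
  expect_equal(ph0$front_to_back, (65 - 5) / 22, tolerance = 0.02)
  expect_equal(ph0$entrance_time, template_entrance_time(bs0, 2.5), tolerance = 0.02)
  # shortened holding shows up in the holding phase, not the sprint
  short <- segment_phases(generate_behavior_session(
    behavior_spec(n_trials = 40, holding_duration = c(1.27, 0.25), seed = 7)))
  expect_lt(median(short$holding, na.rm = TRUE), median(ph$holding, na.rm = TRUE) - 0.5)
  expect_equal(median(short$back_to_front, na.rm = TRUE),
               median(ph$back_to_front, na.rm = TRUE), tolerance = 0.15)
})

test_that("speed statistics follow the treadmill kinematics", {
  # holding position on a 22 cm/s belt: locomotor speed 22 throughout
  tr <- tibble::tibble(time_s = seq(0, 20, 0.01), position_cm = 40)
  ss <- speed_statistics(tr)
  expect_equal(ss$max_speed, 22)
  expect_equal(ss$distance_cm, 22 * ss$duration_s, tolerance = 1e-6)
  expect_equal(sum(ss$occupancy$proportion), 1)
  # running forward against the belt at a constant 30 cm/s
  tr2 <- tibble::tibble(time_s = seq(0, 20, 0.01),
                        position_cm = 170 - 8 * seq(0, 20, 0.01))
  ss2 <- speed_statistics(tr2)
  expect_equal(ss2$max_speed, 30, tolerance = 1e-6)
  expect_equal(ss2$distance_cm, 600, tolerance = 2)
  expect_error(speed_statistics(tr[0, ]), "two or more")
})
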