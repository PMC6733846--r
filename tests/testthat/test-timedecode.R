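test_that("trajectory splits are disjoint partitions, reproducible per seed", {
  cfg <- decoder_config()
  s1 <- split_trajectories(50, cfg, seed = 1)
  expect_length(s1$train, 20)
  expect_length(s1$comparison, 30)
  expect_length(intersect(s1$train, s1$comparison), 0)
  expect_setequal(c(s1$train, s1$comparison), 1:50)
  expect_identical(s1, split_trajectories(50, cfg, seed = 1))
  expect_error(split_trajectories(40, cfg), "at least 50")
})

test_that("the decoder builds all pairwise classifiers and matches libsvm votes", {
  set.seed(2)
  X <- matrix(rnorm(1200 * 6), 1200, 6) +
    outer(rep(seq(0, 29.5, 0.5), each = 20), rep(1, 6))
  y <- rep(1:60, each = 20)
  dec <- train_time_decoder(X, y)
  expect_equal(dec$n_pairs, choose(60, 2))
  expect_equal(dec$n_pairs, 1770)
  mine <- predict(dec, X)
  ref <- as.integer(as.character(predict(dec$fit, X)))
  expect_equal(mine, ref)
})

test_that("separable training data are self-classified perfectly; ties go to the lowest bin", {
  centers <- matrix(rnorm(10 * 3, sd = 10), 10, 3)
  X <- centers[rep(1:10, each = 5), ] + rnorm(150, sd = 0.01)
  y <- rep(1:10, each = 5)
  dec <- train_time_decoder(X, y)
  sc <- score_decoder(dec, X, y)
  expect_equal(sc$mean_accuracy, 1)
  # equal vote counts fall to the lowest bin label: a 3-class voting cycle
  dec_cycle <- matrix(c(1, 1, -1), 1, 3)  # 1 beats 2, 2 beats 3, 3 beats 1
  expect_equal(popclock:::vote_bins(dec_cycle, c(1, 2, 1), c(2, 3, 3), c(4L, 9L, 2L)),
               2L)
  # and with distinct counts the majority wins regardless of label order
  dec_maj <- matrix(c(-1, -1, -1), 1, 3)
  expect_equal(popclock:::vote_bins(dec_maj, c(1, 2, 1), c(2, 3, 3), c(4L, 9L, 2L)),
               2L)
})

test_that("shuffled labels decode at chance", {
  set.seed(3)
  pr <- generate_protocol(stim_protocol(), seed = 2)
  fx <- acceptance_fixtures()
  pv <- subset_cells(fx$pv_seq, 1:60)
  d <- dim(pv$rates)
  # shuffle the bin labels of the training and comparison observations
  split <- split_trajectories(d[3], decoder_config(), seed = 4)
  Xtr <- t(matrix(pv$rates[, , split$train], d[1], 60 * 20))
  Xc <- t(matrix(pv$rates[, , split$comparison], d[1], 60 * 30))
  p <- prcomp(Xtr)
  k <- 10
  ytr <- sample(rep(1:60, 20))
  dec <- train_time_decoder(p$x[, 1:k], ytr)
  pred <- predict(dec, sweep(Xc, 2, p$center) %*% p$rotation[, 1:k])
  acc <- mean(pred == rep(1:60, 30))
  se <- sqrt((1 / 60) * (59 / 60) / 1800)
  expect_lt(abs(acc - 1 / 60), 4 * se + 0.01)
})

test_that("time-shift surrogates conserve spike counts and a zero shift is a no-op", {
  fx <- acceptance_fixtures()
  sp <- fx$spikes_seq
  sur <- make_surrogate(sp, fx$protocol, "time_shift", seed = 5)
  expect_equal(dplyr::count(sur$spikes, cell_id),
               dplyr::count(sp, cell_id))
  sur0 <- make_surrogate(sp, fx$protocol, "time_shift",
                         shift_range = c(0, 0), seed = 5)
  expect_equal(sort(sur0$spikes$time_s), sort(sp$time_s))
  # no-stim windows avoid all stimuli
  surn <- make_surrogate(sp, fx$protocol, "no_stim_random", seed = 6)
  stim <- fx$protocol$events$time_s
  for (t0 in surn$train_onsets) {
    expect_false(any(stim >= t0 - 1 & stim < t0 + 2))
  }
  # post-train windows sit 2 s after each train's last stimulus
  surp <- make_surrogate(sp, fx$protocol, "post_train")
  last <- tapply(fx$protocol$events$time_s, fx$protocol$events$train_id, max)
  expect_equal(unname(surp$train_onsets), as.numeric(sort(last)) + 2)
})

test_that("post-stimulus blanking removes exactly the spikes in the blank windows", {
  fx <- acceptance_fixtures()
  sp <- dplyr::filter(fx$spikes_seq, cell_id %in% unique(cell_id)[1:20])
  out <- remove_post_stimulus_spikes(sp, fx$protocol, blank_ms = 50)
  stim <- fx$protocol$events$time_s
  in_blank <- vapply(sp$time_s, function(t) {
    any(t - stim >= 0 & t - stim < 0.05)
  }, logical(1))
  expect_equal(nrow(out), sum(!in_blank))
  # a cell firing only in baseline is untouched
  base_cell <- spike_tbl(c(1, 2, 3))
  expect_equal(nrow(remove_post_stimulus_spikes(base_cell, fx$protocol)), 3)
  # a cell firing only within the blank window is emptied
  blank_cell <- spike_tbl(stim[1:5] + 0.01)
  expect_equal(nrow(remove_post_stimulus_spikes(blank_cell, fx$protocol)), 0)
})

test_that("decoding is deterministic per seed and reports per-bin scores", {
  fx <- acceptance_fixtures()
  pv <- subset_cells(fx$pv_seq, 1:40)
  r1 <- decode_elapsed_time(pv, seed = 7)
  r2 <- decode_elapsed_time(pv, seed = 7)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  expect_equal(nrow(r1$per_bin), 60)
  expect_true(all(r1$per_bin$score >= 0 & r1$per_bin$score <= 1))
  expect_equal(glance(r1)$chance, 1 / 60)
})
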