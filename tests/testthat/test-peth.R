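test_that("PETH alignment and geometry are exact", {
  # spike exactly at the event time lands in bin [0, 1)
  p <- build_peth(5, events = 5)
  expect_equal(length(p$counts), 1300)
  expect_equal(p$counts[p$bin_starts == 0], 1)
  expect_equal(sum(p$counts), 1)
  # counts conserved: all aligned spikes inside the window are counted once
  ev <- c(10, 20, 30)
  sp <- sort(runif(500, 8, 32))
  p2 <- build_peth(sp, ev)
  brute <- sum(vapply(ev, function(e) {
    sum(sp - e >= -1 & sp - e < 0.3)
  }, numeric(1)))
  expect_equal(sum(p2$counts), brute)
  expect_error(build_peth(1, events = numeric(0)), "at least one")
  expect_error(build_peth(1, events = 5, bin_width = 7), "divide")
})

test_that("homogeneous Poisson spiking gives flat PETHs at the expected level", {
  set.seed(1)
  ev <- seq(2, 2 + 49 * 1.4, by = 1.4)
  dur <- max(ev) + 1
  sp <- sort(runif(rpois(1, 10 * dur), 0, dur))
  p <- build_peth(sp, ev)
  expected <- 10 * 0.001 * 50        # rate x bin width x events
  se <- sqrt(expected / length(p$counts))
  expect_lt(abs(mean(p$counts) - expected), 3 * se)
})

test_that("baseline limits follow the chosen rule", {
  p <- build_peth(numeric(0), events = 5)
  p$counts <- rep(3L, 1300)
  lim <- baseline_limits(p)
  expect_equal(c(lim$lower, lim$baseline_mean, lim$upper), c(3, 3, 3))
  # level 100 percentile rule gives min/max
  set.seed(2)
  p$counts <- rpois(1300, 4)
  lim100 <- baseline_limits(p, level = 100, method = "percentile")
  base <- p$counts[p$bin_starts < 0]
  expect_equal(lim100$lower, min(base))
  expect_equal(lim100$upper, max(base))
  # normal rule at large lambda matches mean + 2.576 sd of a Poisson
  set.seed(3)
  p$counts <- rpois(1300, 400)
  limn <- baseline_limits(p, method = "normal")
  expect_equal(limn$upper, 400 + 2.576 * 20, tolerance = 0.05)
})

test_that("classify_response recovers kernel onsets exactly from noiseless rates", {
  pr <- tiny_protocol(n_trains = 1, n_stimuli = 1)
  pop <- population_spec(n_cells = 4, structure = "stereotyped", gain = 3,
                         baseline_rate = 40, seed = 1)
  cells <- draw_population_cells(pop, pr)
  cells$archetype <- c("short_excitation", "excitation_pause_rebound",
                       "pause_late_excitation", "pause_only")
  cells$latency_ms <- rep(19, 4)
  cells$exc1_onset <- c(19, 19, NA, NA)
  cells$pause_start <- c(NA, 31, 19, 19)
  cells$pause_end <- c(NA, 81, 100, 99)
  cells$exc2_onset <- c(NA, 86, 150, NA)
  cells$exc2_gain <- c(NA, 0.7, 1, NA)
  centers <- seq(-999.5, 299.5, by = 1)
  n_ev <- 500
  rates <- evoked_rate(cells, centers, baseline_rate = 40)
  labels <- vapply(seq_len(4), function(i) {
    p <- build_peth(numeric(0), events = 0)
    p$counts <- rates[i, ] * 0.001 * n_ev
    p$n_events <- n_ev
    lim <- baseline_limits(p)
    prof <- classify_response(p, lim)
    expect_true(prof$responsive)
    expect_equal(prof$latency_ms, 19)
    classify_response_type(p, lim)
  }, character(1))
  expect_equal(labels, cells$archetype)
})

test_that("a sampled short-excitation cell yields latency 19 +/- 1 ms", {
  pr <- single_stim_protocol(n = 250)
  pop <- population_spec(n_cells = 1, structure = "stereotyped", gain = 8,
                         baseline_rate = 2, peak_jitter_ms = 0.3,
                         archetype_mix = pure_excitation_mix, seed = 3)
  cells <- draw_population_cells(pop, pr)
  cells$latency_ms <- 19; cells$exc1_onset <- 19
  sp <- generate_population_spikes(pop, pr, cells = cells)
  prof <- classify_response(build_peth(sp$time_s, pr$events$time_s))
  expect_true(prof$responsive)
  expect_equal(prof$direction, "excitation")
  expect_lt(abs(prof$latency_ms - 19), 1 + 1e-9)
})

test_that("a pause-only cell with solid baseline is detected through the lower limit", {
  pr <- single_stim_protocol(n = 200)
  mix <- c(short_excitation = 0, excitation_pause_rebound = 0,
           pause_late_excitation = 0, pause_only = 1)
  pop <- population_spec(n_cells = 1, structure = "stereotyped",
                         baseline_rate = 60, pause_depth = 1,
                         archetype_mix = mix, seed = 4)
  cells <- draw_population_cells(pop, pr)
  cells$latency_ms <- 20; cells$pause_start <- 20; cells$pause_end <- 100
  sp <- generate_population_spikes(pop, pr, cells = cells)
  prof <- classify_response(build_peth(sp$time_s, pr$events$time_s), min_run = 2)
  expect_true(prof$responsive)
  expect_equal(prof$direction, "suppression")
  expect_lt(abs(prof$latency_ms - 20), 4)
})

test_that("type-I rate of the limit rule matches its brute-force expectation", {
  set.seed(5)
  ev <- seq(2, 2 + 49 * 1.4, by = 1.4)
  dur <- max(ev) + 1
  lambda <- 10 * 0.001 * 50
  profs <- purrr::map_df(1:500, function(i) {
    sp <- sort(runif(rpois(1, 10 * dur), 0, dur))
    p <- build_peth(sp, ev)
    lim <- baseline_limits(p)
    dplyr::bind_cols(classify_response(p, lim),
                     classify_response(p, lim, min_run = 2) |>
                       dplyr::rename_with(~ paste0(.x, "2")))
  })
  # independent oracle: the rule applied to raw Poisson counts
  oracle <- mean(vapply(1:4000, function(i) {
    b <- rpois(1000, lambda)
    up <- quantile(b, 0.995, type = 1); lo <- quantile(b, 0.005, type = 1)
    r <- rpois(295, lambda)
    any(r > up | r < lo)
  }, logical(1)))
  expect_lt(abs(mean(profs$responsive) - oracle), 0.07)
  # requiring 2 consecutive significant bins controls the per-cell error
  expect_lte(mean(profs$responsive2), 0.05)
})

test_that("latency is invariant to spikes outside the analysis window", {
  sp <- c(4.5, 5.021, 5.025)
  p1 <- classify_response(build_peth(sp, 5), baseline_limits(build_peth(sp, 5)))
  sp2 <- c(sp, 5.8, 9, 0.2)
  p2 <- classify_response(build_peth(sp2, 5), baseline_limits(build_peth(sp2, 5)))
  expect_equal(p1$latency_ms, p2$latency_ms)
})

test_that("latency summaries aggregate and restrict correctly", {
  profiles <- tibble::tibble(
    region = c("S1", "S1", "DLS"), responsive = c(TRUE, FALSE, TRUE),
    latency_ms = c(19, NA, 42))
  ls <- latency_summary(profiles)
  expect_equal(ls$summary$median_latency_ms[ls$summary$region == "S1"], 19)
  expect_equal(ls$summary$responsive_pct[ls$summary$region == "S1"], 50)
  ls30 <- latency_summary(profiles, max_latency_ms = 30)
  expect_true(is.na(ls30$summary$median_latency_ms[ls30$summary$region == "DLS"]))
  none <- latency_summary(dplyr::mutate(profiles, responsive = FALSE))
  expect_equal(nrow(none$histogram), 0)
  expect_true(all(is.na(none$summary$median_latency_ms)))
})
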