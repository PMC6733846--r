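test_that("population binning geometry and totals are exact", {
  # single spike at the train onset: 20 spikes/s in the bin starting at 0
  pv <- bin_population(spike_tbl(c(10)), train_onsets = 10)
  expect_equal(dim(pv$rates), c(1, 60, 1))
  expect_equal(which(pv$rates[1, , 1] > 0), which(pv$bin_starts == 0))
  expect_equal(max(pv$rates), 1 / 0.05)
  # totals conserved across an arbitrary spike set
  set.seed(1)
  onsets <- c(10, 20, 35)
  sp <- tibble::tibble(cell_id = sample(c("a", "b"), 400, TRUE),
                       time_s = runif(400, 8, 40))
  pv2 <- bin_population(sp, onsets)
  inside <- sum(vapply(onsets, function(o) {
    sum(sp$time_s >= o - 1 & sp$time_s < o + 2)
  }, numeric(1)))
  expect_equal(sum(pv2$rates) * 0.05, inside)
  expect_error(bin_population(sp, onsets, bin_width = 0.07), "divide")
})

test_that("Z-scoring normalises cells and recovers the sequential ordering", {
  pr <- generate_protocol(stim_protocol(n_trains = 40), seed = 3)
  pop <- population_spec(n_cells = 100, structure = "sequential", gain = 15,
                         baseline_rate = 2, peak_jitter_ms = 0,
                         archetype_mix = pure_excitation_mix, seed = 7)
  cells <- draw_population_cells(pop, pr)
  # every cell responds to every stimulus at its preferred phase, so the
  # first inter-stimulus cycle carries the tiling
  cells$gain_profile <- rep(list(rep(1, 5)), nrow(cells))
  sp <- generate_population_spikes(pop, pr, cells = cells)
  pv <- bin_population(sp, pr)
  zs <- suppressMessages(zscore_and_sort(pv))
  # non-degenerate rows have mean 0, sd 1 over the reference window
  i <- setdiff(seq_along(pv$cells), match(zs$flagged, pv$cells))[1]
  v <- as.vector(zs$z[i, , ])
  expect_equal(mean(v), 0, tolerance = 1e-10)
  expect_equal(sd(v), 1, tolerance = 1e-10)
  # ordering tracks the generator-assigned phase (cells whose response peak
  # wraps past the cycle boundary are excluded from the comparison)
  resp_peak <- cells$phase_ms[match(pv$cells, cells$cell_id)] +
    cells$latency_ms[match(pv$cells, cells$cell_id)]
  keep <- !pv$cells %in% zs$flagged & resp_peak < 280
  rho <- cor(zs$peak_time_s[keep], resp_peak[keep], method = "spearman")
  expect_gt(rho, 0.9)
  # constant-rate cell maps to an all-zero flagged row
  pvc <- bin_population(spike_tbl(5), 10)
  pvc$rates[1, , 1] <- 5
  zc <- suppressMessages(zscore_and_sort(pvc))
  expect_true(all(zc$z == 0))
  expect_equal(zc$flagged, pvc$cells)
})

test_that("PCA trajectories satisfy rank, optimality and ordering invariances", {
  set.seed(4)
  # rank-2 data: first two components carry all variance
  pv <- bin_population(spike_tbl(numeric(0), cell = "x"), 10)
  base <- matrix(rnorm(60 * 2), 60, 2)
  load2 <- matrix(rnorm(2 * 5), 2, 5)
  pv$rates <- array(t(base %*% load2), dim = c(5, 60, 1))
  pv$cells <- paste0("c", 1:5)
  traj <- pca_trajectories(pv)
  expect_equal(sum(traj$explained_variance[1:2]), 1, tolerance = 1e-10)
  expect_true(all(diff(traj$explained_variance) < 1e-10))
  # reconstruction error decreases monotonically in k
  X <- t(matrix(pv$rates, 5, 60))
  p <- prcomp(X)
  errs <- vapply(1:5, function(k) {
    R <- p$x[, 1:k, drop = FALSE] %*% t(p$rotation[, 1:k, drop = FALSE])
    sum((scale(X, scale = FALSE) - R)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # trajectories invariant (up to sign) to cell ordering
  perm <- c(3, 1, 5, 2, 4)
  pvp <- pv; pvp$rates <- pv$rates[perm, , , drop = FALSE]; pvp$cells <- pv$cells[perm]
  tp <- pca_trajectories(pvp)
  for (k in 1:2) {
    expect_equal(abs(tp$scores[, k, 1]), abs(traj$scores[, k, 1]), tolerance = 1e-8)
  }
  # degenerate input errors
  pv0 <- pv; pv0$rates[] <- 3
  expect_error(pca_trajectories(pv0), "zero variance")
})

test_that("stimulus-state extraction yields one state per (train, stimulus)", {
  pr <- generate_protocol(stim_protocol(), seed = 2)
  pop <- population_spec(n_cells = 20, seed = 5)
  pv <- bin_population(generate_population_spikes(pop, pr), pr)
  st <- extract_stimulus_states(pca_trajectories(pv), pr)
  expect_equal(nrow(st), 250)
  expect_equal(nrow(dplyr::distinct(st, train_id, stim_index)), 250)
  # a stimulus on a bin edge belongs to the bin starting there: the first
  # stimulus sits at relative time 0 and must map to the bin starting at 0
  pr1 <- tiny_protocol(n_trains = 1, n_stimuli = 1)
  sp1 <- dplyr::bind_rows(spike_tbl(pr1$train_onsets + c(0.01, 0.3), cell = "a"),
                          spike_tbl(pr1$train_onsets + c(0.06, 0.8), cell = "b"))
  pv1 <- bin_population(sp1, pr1)
  tr1 <- pca_trajectories(pv1)
  st1 <- extract_stimulus_states(tr1, pr1, n_components = 1)
  expect_equal(nrow(st1), 1)
  b0 <- which(pv1$bin_starts == 0)
  expect_equal(st1$pc1, tr1$scores[b0, 1, 1])
})

test_that("silhouette coefficients obey the formula limits and match cluster::silhouette", {
  # two tight clusters: SC = 1 everywhere
  x <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  lab <- rep(1:2, each = 3)
  expect_equal(silhouette_coefficients(x, lab), rep(1, 6))
  # a point equidistant in mean to its own and the nearest cluster: SC = 0
  x2 <- rbind(c(0, 0), c(2, 0), c(1, 0), c(1, 1), c(1, -1))
  lab2 <- c(1, 1, 1, 2, 2)
  sc2 <- silhouette_coefficients(x2, lab2)
  expect_equal(sc2[3], 0)
  # bounded in [-1, 1] and equal to the reference implementation
  set.seed(6)
  x3 <- matrix(rnorm(40), 20, 2)
  lab3 <- sample(1:4, 20, replace = TRUE)
  while (any(tabulate(lab3, 4) < 2)) lab3 <- sample(1:4, 20, replace = TRUE)
  mine <- silhouette_coefficients(x3, lab3)
  expect_true(all(mine >= -1 & mine <= 1))
  ref <- cluster::silhouette(lab3, dist(x3))[, "sil_width"]
  expect_equal(mine, unname(ref), tolerance = 1e-12)
  expect_error(silhouette_coefficients(x3, rep(1, 20)), "two clusters")
})

test_that("observed stimulus labels beat every random assignment on separated states", {
  # brute force on a tiny instance: all label permutations of 12 separated states
  set.seed(7)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- centers[rep(1:3, each = 4), ] + rnorm(24, sd = 0.1)
  true_lab <- rep(1:3, each = 4)
  obs <- mean(silhouette_coefficients(x, true_lab))
  expect_gt(obs, 0.95)
  rand <- replicate(200, {
    lab <- sample(true_lab)
    mean(silhouette_coefficients(x, lab))
  })
  # no permuted labelling scores higher; non-equivalent ones score clearly lower
  expect_true(all(rand <= obs + 1e-12))
  expect_gt(obs, max(rand[rand < obs - 1e-9]) + 0.5)
})

test_that("silhouette_analysis separates observed from randomised assignments", {
  pr <- generate_protocol(stim_protocol(n_trains = 20), seed = 2)
  pop <- population_spec(n_cells = 60, structure = "sequential", gain = 4, seed = 8)
  pv <- bin_population(generate_population_spikes(pop, pr), pr)
  st <- extract_stimulus_states(pca_trajectories(pv), pr)
  sa <- silhouette_analysis(st, n_random = 20, seed = 9)
  expect_true(all(sa$observed$sc >= -1 & sa$observed$sc <= 1, na.rm = TRUE))
  expect_gt(sa$observed_mean, max(sa$random$mean_sc))
  expect_equal(sort(unique(sa$random$k)), 3:7)
  expect_true(glance(sa)$observed_exceeds_all_k)
})

test_that("per-stimulus similarity is 1 for identical responses and NA for empty ones", {
  pr <- tiny_protocol(n_trains = 4, n_stimuli = 3, rate = 2, seed = 1)
  # craft spikes: the same pattern after every stimulus
  ev <- pr$events$time_s
  sp <- spike_tbl(sort(c(ev + 0.01, ev + 0.02, ev + 0.21)))
  pv <- bin_population(sp, pr)
  ps <- per_stimulus_similarity(pv, pr)
  expect_equal(nrow(ps), 12)
  expect_true(all(abs(ps$r - 1) < 1e-12))
  # remove all spikes of one stimulus: its pattern has no variance -> NA
  drop <- pr$events$time_s[1]
  sp2 <- sp[!(sp$time_s >= drop & sp$time_s < drop + 0.5), ]
  pv2 <- bin_population(sp2, pr)
  ps2 <- suppressMessages(per_stimulus_similarity(pv2, pr))
  expect_true(is.na(ps2$r[1]))
})
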