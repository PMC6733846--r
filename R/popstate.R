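# robust half-open binning: index of [edge, edge + width) containing x,
# tolerant to floating-point representation of edges
bin_index <- function(x, origin, width) {
  as.integer(floor((x - origin) / width + 1e-9)) + 1L
}

#' Build temporal population vectors around each train
#'
#' Spike counts per cell in non-overlapping bins (50 ms by default) within a
#' window around each train onset (-1 to +2 s by default, i.e. 60 bins),
#' converted to rates (spikes/s). All cells appear in every train's matrix.
#'
#' @param spikes A spike table (`cell_id`, `time_s`).
#' @param train_onsets Numeric vector of train-onset times, s (or a realised
#'   [stim_protocol()]).
#' @param window Length-2 window relative to each onset, s.
#' @param bin_width Bin width, s; must divide the window length.
#' @return A `pop_vectors` object: list with `rates` (array cells x bins x
#'   trains, spikes/s), `cells`, `bin_starts` (s, relative to onset),
#'   `bin_width`, `window`, `train_onsets`.
#' @export
bin_population <- function(spikes, train_onsets, window = c(-1, 2),
                           bin_width = 0.05) {
  assert_spike_table(spikes)
  if (inherits(train_onsets, "stim_protocol")) train_onsets <- train_onsets$train_onsets
  if (is.null(train_onsets) || length(train_onsets) < 1) {
    abort("`train_onsets` must contain at least one onset.")
  }
  n_bins <- diff(window) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-6) {
    abort("`bin_width` must divide the window length exactly.")
  }
  n_bins <- as.integer(round(n_bins))
  cells <- sort(unique(spikes$cell_id))
  n_cells <- length(cells)
  n_trains <- length(train_onsets)

  tr <- findInterval(spikes$time_s, train_onsets + window[1])
  ok <- tr >= 1 & spikes$time_s < train_onsets[pmax(tr, 1)] + window[2] - 1e-12
  tr_ok <- tr[ok]
  b <- bin_index(spikes$time_s[ok], train_onsets[tr_ok] + window[1], bin_width)
  ok2 <- b >= 1 & b <= n_bins
  ci <- match(spikes$cell_id[ok], cells)[ok2]
  idx <- ci + (b[ok2] - 1L) * n_cells + (tr_ok[ok2] - 1L) * n_cells * n_bins
  counts <- tabulate(idx, nbins = n_cells * n_bins * n_trains)
  rates <- array(counts / bin_width, dim = c(n_cells, n_bins, n_trains),
                 dimnames = list(cells, NULL, NULL))
  structure(
    list(rates = rates, cells = cells,
         bin_starts = window[1] + bin_width * (seq_len(n_bins) - 1),
         bin_width = bin_width, window = window, train_onsets = train_onsets),
    class = "pop_vectors"
  )
}

#' @export
print.pop_vectors <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<pop_vectors> %d cells x %d bins (%g ms) x %d trains\n",
              d[1], d[2], 1000 * x$bin_width, d[3]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pop_vectors <- function(x, ...) {
  d <- dim(x$rates)
  tidyr::expand_grid(train_id = seq_len(d[3]), bin = seq_len(d[2]),
                     cell_id = x$cells) |>
    mutate(time_s = x$bin_starts[.data$bin],
           rate = as.vector(x$rates)[
             match(.data$cell_id, x$cells) +
               (.data$bin - 1) * d[1] + (.data$train_id - 1) * d[1] * d[2]])
}

#' Z-score population rates and order cells by peak time
#'
#' Each cell's rates are Z-scored against its mean and SD over a reference
#' window (all bins and trains pooled; full window by default). Cells with zero
#' SD are mapped to 0 and flagged. Cells are ordered by the time of their
#' trial-averaged peak inside a sorting window, by convention the first
#' inter-stimulus cycle after the first stimulus.
#'
#' @param pv A [bin_population()] object.
#' @param reference_window Window (s, relative to onset) defining the Z-score
#'   reference statistics; default the full window.
#' @param sort_window Window (s) in which the peak time is measured; default
#'   `[0, 0.303)` (one 3.3-Hz cycle).
#' @return A list: `z` (array like `rates`), `order` (cell indices sorted by
#'   peak time), `peak_time_s` per cell, `flagged` (cells with zero SD).
#' @export
zscore_and_sort <- function(pv, reference_window = NULL,
                            sort_window = c(0, 1 / 3.3)) {
  ref <- reference_window %||% pv$window
  sel <- pv$bin_starts >= ref[1] & pv$bin_starts < ref[2]
  d <- dim(pv$rates)
  z <- pv$rates
  mu <- numeric(d[1]); sdev <- numeric(d[1])
  for (i in seq_len(d[1])) {
    v <- as.vector(pv$rates[i, sel, ])
    mu[i] <- mean(v); sdev[i] <- sd(v)
    z[i, , ] <- if (sdev[i] > 0) (pv$rates[i, , ] - mu[i]) / sdev[i] else 0
  }
  flagged <- pv$cells[sdev == 0]
  if (length(flagged) > 0) {
    inform(sprintf("%d cell(s) with zero variance mapped to Z = 0.", length(flagged)))
  }
  zbar <- apply(z, c(1, 2), mean)
  ssel <- which(pv$bin_starts >= sort_window[1] & pv$bin_starts < sort_window[2])
  peak_bin <- ssel[apply(zbar[, ssel, drop = FALSE], 1, which.max)]
  peak_time <- pv$bin_starts[peak_bin]
  list(z = z, order = order(peak_time), peak_time_s = peak_time, flagged = flagged)
}

#' PCA state-space trajectories of population activity
#'
#' One PCA basis is fitted on the population vectors of all trains pooled
#' (bins x trains observations, cells as variables), so that states from
#' different trains live in a common space; each train's trajectory is the
#' projection of its 60 vectors onto that basis. A per-train fit is available
#' behind `pooled = FALSE`.
#'
#' @param pv A [bin_population()] object with at least 2 cells.
#' @param n_components Number of components retained in the scores; default all.
#' @param pooled Fit one shared basis on all trains (default) or one per train.
#' @return A `pca_trajectories` object: `scores` (array bins x components x
#'   trains), `explained_variance` (fractions, non-increasing), `loadings`
#'   (cells x components), plus the binning metadata of `pv`. With
#'   `pooled = FALSE`, `scores`/`loadings`/`explained_variance` are lists per
#'   train.
#' @export
pca_trajectories <- function(pv, n_components = NULL, pooled = TRUE) {
  d <- dim(pv$rates)
  if (d[1] < 2) abort("PCA needs at least 2 cells.")
  X <- t(matrix(pv$rates, d[1], d[2] * d[3]))  # rows: bin fastest, then train
  if (all(abs(X - rep(colMeans(X), each = nrow(X))) < 1e-12)) {
    abort("Population activity has zero variance; PCA is undefined for these data.")
  }
  k_max <- min(d[1], nrow(X))
  nc <- min(n_components %||% k_max, k_max)
  if (pooled) {
    p <- prcomp(X, center = TRUE, scale. = FALSE)
    ev <- p$sdev^2 / sum(p$sdev^2)
    scores <- array(p$x[, seq_len(nc), drop = FALSE], dim = c(d[2], d[3], nc))
    scores <- aperm(scores, c(1, 3, 2))
    out <- list(scores = scores, explained_variance = ev,
                loadings = p$rotation[, seq_len(nc), drop = FALSE],
                center = p$center, pooled = TRUE)
  } else {
    fits <- lapply(seq_len(d[3]), function(t) {
      prcomp(t(pv$rates[, , t]), center = TRUE, scale. = FALSE)
    })
    out <- list(
      scores = lapply(fits, function(p) p$x[, seq_len(min(nc, ncol(p$x))), drop = FALSE]),
      explained_variance = lapply(fits, function(p) p$sdev^2 / sum(p$sdev^2)),
      loadings = lapply(fits, function(p) p$rotation),
      pooled = FALSE
    )
  }
  out <- c(out, list(cells = pv$cells, bin_starts = pv$bin_starts,
                     bin_width = pv$bin_width, window = pv$window,
                     train_onsets = pv$train_onsets))
  structure(out, class = "pca_trajectories")
}

#' @export
print.pca_trajectories <- function(x, ...) {
  if (x$pooled) {
    cat(sprintf("<pca_trajectories> %d trains x %d bins, %d components (%.0f%% var in first 2)\n",
                dim(x$scores)[3], dim(x$scores)[1], dim(x$scores)[2],
                100 * sum(x$explained_variance[1:2])))
  } else {
    cat(sprintf("<pca_trajectories> per-train basis, %d trains\n", length(x$scores)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_trajectories <- function(x, ...) {
  if (!x$pooled) abort("tidy() supports pooled trajectories.")
  d <- dim(x$scores)
  out <- tidyr::expand_grid(train_id = seq_len(d[3]), bin = seq_len(d[1]))
  out$time_s <- x$bin_starts[out$bin]
  for (k in seq_len(d[2])) {
    out[[paste0("pc", k)]] <- as.vector(x$scores[out$bin + (k - 1) * d[1] +
                                                   (out$train_id - 1) * d[1] * d[2]])
  }
  out
}

#' Extract low-dimensional population states at stimulus times
#'
#' For each (train, stimulus) pair the trajectory point of the bin containing
#' the stimulus time is taken (half-open bins; a stimulus on a bin edge belongs
#' to the bin starting there), yielding exactly
#' `n_trains * n_stimuli` states.
#'
#' @param traj A pooled [pca_trajectories()] object.
#' @param protocol The realised [stim_protocol()] that aligned the trains.
#' @param n_components Number of components retained per state.
#' @return A `stimulus_states` tibble: `train_id`, `stim_index`, `pc1..pck`.
#' @export
extract_stimulus_states <- function(traj, protocol, n_components = 2) {
  if (!inherits(traj, "pca_trajectories") || !traj$pooled) {
    abort("`traj` must be a pooled `pca_trajectories` object.")
  }
  nc <- min(n_components, dim(traj$scores)[2])
  ev <- protocol$events
  rel <- ev$time_s - traj$train_onsets[ev$train_id]
  b <- bin_index(rel, traj$window[1], traj$bin_width)
  if (any(b < 1 | b > dim(traj$scores)[1])) {
    abort("Some stimulus times fall outside the trajectory window.")
  }
  out <- tibble(train_id = ev$train_id, stim_index = ev$stim_index)
  d <- dim(traj$scores)
  for (k in seq_len(nc)) {
    out[[paste0("pc", k)]] <-
      traj$scores[b + (k - 1) * d[1] + (ev$train_id - 1) * d[1] * d[2]]
  }
  class(out) <- c("stimulus_states", class(out))
  out
}

#' Silhouette coefficients from Euclidean distances
#'
#' For each point, `SC = (d' - d) / max(d, d')` where `d` is its mean distance
#' to the other members of its own cluster and `d'` the smallest mean distance
#' to the members of any other cluster. Values lie in `[-1, 1]`. Points in
#' singleton clusters have an undefined SC and are returned as `NA`.
#'
#' @param x Numeric matrix (points x dimensions) or a precomputed distance
#'   matrix of class `dist`.
#' @param labels Cluster labels, one per point; at least two clusters.
#' @return Numeric vector of per-point silhouette coefficients.
#' @export
silhouette_coefficients <- function(x, labels) {
  D <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  labels <- as.character(labels)
  n <- nrow(D)
  if (length(labels) != n) abort("`labels` must have one entry per point.")
  lev <- unique(labels)
  if (length(lev) < 2) abort("Silhouette needs at least two clusters.")
  sizes <- table(labels)[lev]
  sums <- rowsum(D, group = labels)[lev, , drop = FALSE]  # clusters x points
  own <- match(labels, lev)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[[own[i]]]
    if (ni < 2) { sc[i] <- NA_real_; next }
    d_in <- sums[own[i], i] / (ni - 1)
    d_out <- min(sums[-own[i], i] / sizes[-own[i]])
    denom <- max(d_in, d_out)
    sc[i] <- if (denom == 0) 0 else (d_out - d_in) / denom
  }
  sc
}

#' Silhouette validation of stimulus-indexed population states
#'
#' The observed condition labels each state by its stimulus index and computes
#' per-state silhouette coefficients in the low-dimensional space (first two
#' components by default). Randomised conditions reassign labels uniformly at
#' random for each cluster count in `k_range`, `n_random` times each; a repeat
#' that produces a cluster with fewer than 2 members is redrawn.
#'
#' @param states A [extract_stimulus_states()] tibble.
#' @param k_range Cluster counts for the randomised assignments.
#' @param n_random Number of random assignments per k.
#' @param n_components Number of components used for distances.
#' @param seed Integer seed for the random assignments.
#' @return A `silhouette_analysis` object: `observed` (per-state tibble with
#'   `sc`), `observed_mean`, `random` (tibble `k`, `rep`, `mean_sc`),
#'   `n_redrawn`.
#' @export
silhouette_analysis <- function(states, k_range = 3:7, n_random = 100,
                                n_components = 2, seed = 1L) {
  pc_cols <- grep("^pc\\d+$", names(states), value = TRUE)
  nc <- min(n_components, length(pc_cols))
  x <- as.matrix(states[, pc_cols[seq_len(nc)]])
  D <- stats::dist(x)
  sc_obs <- silhouette_coefficients(D, states$stim_index)
  n <- nrow(x)
  redrawn <- 0L
  random <- withr_seed(seed, {
    purrr::map_df(k_range, function(k) {
      ms <- vapply(seq_len(n_random), function(r) {
        repeat {
          lab <- sample.int(k, n, replace = TRUE)
          if (all(tabulate(lab, k) >= 2)) break
          redrawn <<- redrawn + 1L
        }
        mean(silhouette_coefficients(D, lab), na.rm = TRUE)
      }, numeric(1))
      tibble(k = k, rep = seq_len(n_random), mean_sc = ms)
    })
  })
  if (redrawn > 0) inform(sprintf("%d random assignment(s) redrawn (cluster with < 2 members).", redrawn))
  structure(
    list(observed = mutate(states, sc = sc_obs),
         observed_mean = mean(sc_obs, na.rm = TRUE),
         k_observed = length(unique(states$stim_index)),
         random = random, n_components = nc, n_redrawn = redrawn),
    class = "silhouette_analysis"
  )
}

#' @export
print.silhouette_analysis <- function(x, ...) {
  cat(sprintf("<silhouette_analysis> observed mean SC = %.3f (k = %d); random mean SC range %.3f..%.3f over k = %s\n",
              x$observed_mean, x$k_observed,
              min(x$random$mean_sc), max(x$random$mean_sc),
              paste(range(x$random$k), collapse = "-")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.silhouette_analysis <- function(x, ...) {
  bind_rows(
    tibble(condition = "observed", k = x$k_observed, rep = 1L,
           mean_sc = x$observed_mean),
    mutate(x$random, condition = "randomized", .before = 1)
  )
}

#' @exportS3Method generics::glance
glance.silhouette_analysis <- function(x, ...) {
  rand_by_k <- x$random |> group_by(.data$k) |>
    summarise(mean_sc = mean(.data$mean_sc), .groups = "drop")
  tibble(
    observed_mean_sc = x$observed_mean,
    k_observed = x$k_observed,
    max_random_mean_sc = max(rand_by_k$mean_sc),
    observed_exceeds_all_k = x$observed_mean > max(rand_by_k$mean_sc)
  )
}

#' Similarity of each stimulus response to the average response
#'
#' The single-stimulus population pattern (cells x bins over one inter-stimulus
#' cycle, starting at the bin containing the stimulus) is averaged over all
#' stimuli; the Pearson correlation of each stimulus's pattern with that
#' average quantifies how stereotyped the per-stimulus representation is.
#'
#' @param pv A [bin_population()] object.
#' @param protocol The realised [stim_protocol()].
#' @return A tibble with `train_id`, `stim_index`, `r` (NA when a pattern has
#'   no variance, e.g. zero spikes).
#' @export
per_stimulus_similarity <- function(pv, protocol) {
  cycle_bins <- max(1L, as.integer(floor(1 / protocol$train_rate / pv$bin_width + 1e-9)))
  ev <- protocol$events
  rel <- ev$time_s - pv$train_onsets[ev$train_id]
  b0 <- bin_index(rel, pv$window[1], pv$bin_width)
  n_bins <- dim(pv$rates)[2]
  if (any(b0 < 1 | (b0 + cycle_bins - 1) > n_bins)) {
    abort("A stimulus cycle extends outside the binning window.")
  }
  pats <- vapply(seq_len(nrow(ev)), function(i) {
    as.vector(pv$rates[, b0[i]:(b0[i] + cycle_bins - 1), ev$train_id[i]])
  }, numeric(dim(pv$rates)[1] * cycle_bins))
  avg <- rowMeans(pats)
  r <- apply(pats, 2, function(p) {
    if (sd(p) == 0 || sd(avg) == 0) NA_real_ else cor(p, avg)
  })
  n_na <- sum(is.na(r))
  if (n_na > 0) inform(sprintf("%d stimulus pattern(s) without variance; correlation reported as NA.", n_na))
  tibble(train_id = ev$train_id, stim_index = ev$stim_index, r = r)
}
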