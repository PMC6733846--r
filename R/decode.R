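#' Configuration for the elapsed-time decoder
#'
#' @param n_train Number of trajectories used to train the classifier.
#' @param n_comparison Number of held-out trajectories scored.
#' @param var_explained Fraction of training-set variance the retained
#'   principal components must explain.
#' @param max_pcs Cap on the number of principal components used as features.
#' @param fixed_pcs Optional fixed number of components (overrides the
#'   variance rule).
#' @param raw_features Use raw population vectors instead of PC scores.
#' @param cost Soft-margin cost of the linear SVM.
#' @param tolerance Termination tolerance of the SVM optimiser. The default is
#'   looser than libsvm's 0.001 because majority-vote bin labels are insensitive
#'   to the final digits of the pairwise decision values.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(n_train = 20, n_comparison = 30,
                           var_explained = 0.9, max_pcs = 20,
                           fixed_pcs = NULL, raw_features = FALSE, cost = 1,
                           tolerance = 0.05) {
  check_positive(n_train, "n_train")
  check_positive(n_comparison, "n_comparison")
  check_positive(cost, "cost")
  structure(list(n_train = as.integer(n_train),
                 n_comparison = as.integer(n_comparison),
                 var_explained = var_explained, max_pcs = as.integer(max_pcs),
                 fixed_pcs = fixed_pcs, raw_features = isTRUE(raw_features),
                 cost = cost, tolerance = tolerance),
            class = "decoder_config")
}

#' Split trains into training and comparison trajectories
#'
#' @param n_trains Number of available trajectories, or a [bin_population()]
#'   object.
#' @param cfg A [decoder_config()].
#' @param seed Integer seed.
#' @return A list with integer vectors `train` and `comparison`
#'   (disjoint; sizes per `cfg`).
#' @export
split_trajectories <- function(n_trains, cfg = decoder_config(), seed = 1L) {
  if (inherits(n_trains, "pop_vectors")) n_trains <- dim(n_trains$rates)[3]
  withr_seed(seed, split_trajectories_(n_trains, cfg))
}

split_trajectories_ <- function(n_trains, cfg) {
  need <- cfg$n_train + cfg$n_comparison
  if (n_trains < need) {
    abort(sprintf("Need at least %d trajectories (%d training + %d comparison); got %d.",
                  need, cfg$n_train, cfg$n_comparison, n_trains))
  }
  perm <- sample.int(n_trains)
  list(train = sort(perm[seq_len(cfg$n_train)]),
       comparison = sort(perm[cfg$n_train + seq_len(cfg$n_comparison)]))
}

# rates array -> observations matrix (rows: bin fastest within train)
flatten_trains <- function(pv, trains) {
  d <- dim(pv$rates)
  t(matrix(pv$rates[, , trains, drop = FALSE], d[1], d[2] * length(trains)))
}

#' Keep a subset of cells of a population-vector object
#'
#' @param pv A [bin_population()] object.
#' @param cells Integer indices or cell ids to keep.
#' @return A `pop_vectors` object restricted to those cells.
#' @export
subset_cells <- function(pv, cells) {
  idx <- if (is.numeric(cells)) as.integer(cells) else match(cells, pv$cells)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > dim(pv$rates)[1])) {
    abort("`cells` must index cells present in `pv`.")
  }
  pv$rates <- pv$rates[idx, , , drop = FALSE]
  pv$cells <- pv$cells[idx]
  pv
}

#' Train a one-against-one SVM over population time bins
#'
#' Each training trajectory contributes one observation per 50-ms time bin; a
#' linear binary SVM is trained for every unordered pair of bins (1770 pairs at
#' 60 bins) and prediction proceeds by majority vote with ties broken toward
#' the lowest bin index.
#'
#' @param features Numeric matrix, rows = training observations.
#' @param bins Integer bin label per row.
#' @param cost Soft-margin cost.
#' @param tolerance Optimiser termination tolerance.
#' @return A `time_decoder` object wrapping the fitted pairwise classifiers;
#'   `n_pairs` gives the number of binary problems.
#' @export
train_time_decoder <- function(features, bins, cost = 1, tolerance = 0.05) {
  y <- factor(bins, levels = sort(unique(bins)))
  fit <- e1071::svm(features, y, kernel = "linear", cost = cost,
                    scale = FALSE, tolerance = tolerance)
  nc <- fit$nclasses
  structure(list(fit = fit, n_bins = nc, n_pairs = nc * (nc - 1) / 2,
                 levels = as.integer(levels(y))),
            class = "time_decoder")
}

#' @export
print.time_decoder <- function(x, ...) {
  cat(sprintf("<time_decoder> %d bins, %d pairwise linear SVMs\n",
              x$n_bins, x$n_pairs))
  invisible(x)
}

#' Predict time bins by majority vote over pairwise classifiers
#'
#' The linear weight vector and offset of every pairwise classifier are
#' reconstructed from the fitted support vectors and the decision values for
#' all pairs are computed in one matrix product, then tallied as votes; ties
#' go to the lowest bin index.
#'
#' @param object A [train_time_decoder()] object.
#' @param newdata Numeric matrix of observations to label.
#' @param ... Unused.
#' @return Integer vector of predicted bin labels.
#' @export
predict.time_decoder <- function(object, newdata, ...) {
  fit <- object$fit
  nc <- fit$nclasses
  nSV <- fit$nSV
  start <- c(0L, cumsum(nSV))
  d <- ncol(fit$SV)
  n_pairs <- nc * (nc - 1) / 2
  # per-class coefficient-weighted SV blocks: parts[[c]][k, ] = t(coefs[s_c, k]) %*% SV[s_c, ]
  parts <- lapply(seq_len(nc), function(cl) {
    sc <- (start[cl] + 1):start[cl + 1]
    crossprod(fit$coefs[sc, , drop = FALSE], fit$SV[sc, , drop = FALSE])
  })
  W <- matrix(0, n_pairs, d)
  b <- numeric(n_pairs)
  p <- 0L
  pair_i <- integer(n_pairs); pair_j <- integer(n_pairs)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      p <- p + 1L
      W[p, ] <- parts[[i]][j - 1, ] + parts[[j]][i, ]
      b[p] <- -fit$rho[p]
      pair_i[p] <- i; pair_j[p] <- j
    }
  }
  dec <- newdata %*% t(W) + rep(b, each = nrow(newdata))
  # classes in libsvm's internal order; map to bin labels
  lab <- as.integer(fit$levels[fit$labels])
  vote_bins(dec, pair_i, pair_j, lab)
}

# Tally one-against-one votes: column p of `dec` holds the decision values of
# the (pair_i[p], pair_j[p]) classifier (> 0 votes for pair_i). Ties between
# bins with equal vote counts resolve to the lowest bin label.
vote_bins <- function(dec, pair_i, pair_j, lab) {
  nc <- length(lab)
  pos <- dec > 0
  votes <- vapply(seq_len(nc), function(cl) {
    rowSums(pos[, pair_i == cl, drop = FALSE]) +
      rowSums(!pos[, pair_j == cl, drop = FALSE])
  }, numeric(nrow(dec)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  # order columns by increasing bin label so max.col(ties = first) = lowest bin
  ord <- order(lab)
  votes <- votes[, ord, drop = FALSE]
  sort(lab)[max.col(votes, ties.method = "first")]
}

#' Score a time decoder on comparison trajectories
#'
#' @param decoder A [train_time_decoder()] object.
#' @param features Numeric matrix of comparison observations.
#' @param bins True bin label per row.
#' @return A list: `per_bin` tibble (`bin`, `score`), `mean_accuracy` (mean of
#'   the per-bin correct-label fractions).
#' @export
score_decoder <- function(decoder, features, bins) {
  pred <- predict(decoder, features)
  per_bin <- tibble(bin = bins, correct = pred == bins) |>
    group_by(.data$bin) |>
    summarise(score = mean(.data$correct), .groups = "drop")
  list(per_bin = per_bin, mean_accuracy = mean(per_bin$score))
}

# one full decode: split, PCA on training trains only, SVM, score.
# Uses the current RNG state (callers seed it).
decode_once <- function(pv, cfg) {
  d <- dim(pv$rates)
  split <- split_trajectories_(d[3], cfg)
  Xtr <- flatten_trains(pv, split$train)
  Xcmp <- flatten_trains(pv, split$comparison)
  bins_tr <- rep(seq_len(d[2]), length(split$train))
  bins_cmp <- rep(seq_len(d[2]), length(split$comparison))
  if (cfg$raw_features) {
    Ftr <- Xtr; Fcmp <- Xcmp; k <- ncol(Xtr)
  } else {
    p <- prcomp(Xtr, center = TRUE, scale. = FALSE)
    if (sum(p$sdev^2) <= 0) abort("Training activity has zero variance; cannot decode.")
    ev <- cumsum(p$sdev^2) / sum(p$sdev^2)
    k <- if (!is.null(cfg$fixed_pcs)) cfg$fixed_pcs else which(ev >= cfg$var_explained)[1]
    k <- min(k, cfg$max_pcs, ncol(p$x))
    Ftr <- p$x[, seq_len(k), drop = FALSE]
    Fcmp <- sweep(Xcmp, 2, p$center) %*% p$rotation[, seq_len(k), drop = FALSE]
  }
  dec <- train_time_decoder(Ftr, bins_tr, cost = cfg$cost,
                            tolerance = cfg$tolerance %||% 0.05)
  sc <- score_decoder(dec, Fcmp, bins_cmp)
  structure(list(per_bin = mutate(sc$per_bin, time_s = pv$bin_starts[.data$bin]),
                 mean_accuracy = sc$mean_accuracy, n_cells = d[1], n_pcs = k,
                 split = split, cfg = cfg),
            class = "decoding_result")
}

#' Decode elapsed time from population trajectories
#'
#' Trains are split into training and comparison trajectories, a PCA basis is
#' fitted on the training trajectories only (comparison data are projected onto
#' it, preventing leakage), a one-against-one linear SVM distinguishes every
#' pair of 50-ms time bins, and the comparison bins are labelled by majority
#' vote. The per-bin score is the fraction of that bin's comparison instances
#' labelled correctly; the mean accuracy averages the per-bin scores. Chance
#' level for uniform guessing is `1 / n_bins`.
#'
#' @param pv A [bin_population()] object.
#' @param cfg A [decoder_config()].
#' @param seed Integer seed (controls the split).
#' @return A `decoding_result`: `per_bin` tibble (`bin`, `score`, `time_s`),
#'   `mean_accuracy`, `n_cells`, `n_pcs`, `split`.
#' @export
decode_elapsed_time <- function(pv, cfg = decoder_config(), seed = 1L) {
  withr_seed(seed, decode_once(pv, cfg))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> mean accuracy %.3f over %d bins (%d cells, %d PCs; chance %.3f)\n",
              x$mean_accuracy, nrow(x$per_bin), x$n_cells, x$n_pcs,
              1 / nrow(x$per_bin)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decoding_result <- function(x, ...) x$per_bin

#' @exportS3Method generics::glance
glance.decoding_result <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, n_cells = x$n_cells,
         n_pcs = x$n_pcs, chance = 1 / nrow(x$per_bin))
}

#' Decoding accuracy as a function of population size
#'
#' For each population size, cells are sampled without replacement, population
#' vectors are rebuilt from the sampled cells, and the full decode (split, PCA,
#' SVM, score) is repeated `n_repeats` times with fresh random splits and cell
#' pools. Sizes exceeding the population are truncated with a message.
#'
#' @param pv A [bin_population()] object.
#' @param sizes Integer vector of cell counts; default steps of 10 up to the
#'   population size.
#' @param n_repeats Repeats per size.
#' @param cfg A [decoder_config()].
#' @param seed Integer seed.
#' @param condition Label copied into the output (e.g. `"observed"`,
#'   `"time_shift"`).
#' @return A tibble: `condition`, `n_cells`, `repeat_id`, `mean_accuracy`.
#' @export
population_size_curve <- function(pv, sizes = NULL, n_repeats = 50,
                                  cfg = decoder_config(), seed = 1L,
                                  condition = "observed") {
  n <- dim(pv$rates)[1]
  sizes <- sizes %||% unique(c(seq(10, n, by = 10), n))
  if (any(sizes > n)) {
    inform(sprintf("Sizes above the population (%d cells) truncated.", n))
    sizes <- pmin(sizes, n)
  }
  sizes <- sort(unique(as.integer(sizes)))
  withr_seed(seed, {
    purrr::map_df(sizes, function(s) {
      acc <- vapply(seq_len(n_repeats), function(r) {
        sub <- subset_cells(pv, sample.int(n, s))
        decode_once(sub, cfg)$mean_accuracy
      }, numeric(1))
      tibble(condition = condition, n_cells = s,
             repeat_id = seq_len(n_repeats), mean_accuracy = acc)
    })
  })
}

#' Median and quartiles of a population-size curve
#'
#' @param curve Output of [population_size_curve()] (possibly several
#'   conditions bound together).
#' @return A tibble with per-condition, per-size `median`, `q25`, `q75`.
#' @export
summarise_size_curve <- function(curve) {
  curve |>
    group_by(.data$condition, .data$n_cells) |>
    summarise(median = median(.data$mean_accuracy),
              q25 = quantile(.data$mean_accuracy, 0.25),
              q75 = quantile(.data$mean_accuracy, 0.75),
              .groups = "drop")
}

#' Construct surrogate data for decoding controls
#'
#' Three nulls that destroy stimulus-locked structure while preserving gross
#' spiking statistics: `"time_shift"` shifts all spikes of a cell within each
#' trial by a uniform draw from `shift_range` (spike counts conserved);
#' `"no_stim_random"` keeps the spikes but realigns the analysis to random
#' windows containing no stimulation; `"post_train"` aligns to a fixed point
#' 2 s after the last stimulus of each train.
#'
#' @param spikes A spike table.
#' @param protocol The realised [stim_protocol()].
#' @param kind One of `"time_shift"`, `"no_stim_random"`, `"post_train"`.
#' @param shift_range Uniform range (s) of the positive time shift.
#' @param n_trials Number of random alignment windows for `"no_stim_random"`.
#' @param window Analysis window (s) the alignments must accommodate.
#' @param seed Integer seed.
#' @return A list with `spikes` and `train_onsets` to feed [bin_population()],
#'   plus `kind`.
#' @export
make_surrogate <- function(spikes, protocol,
                           kind = c("time_shift", "no_stim_random", "post_train"),
                           shift_range = c(1, 3), n_trials = 50,
                           window = c(-1, 2), seed = 1L) {
  kind <- match.arg(kind)
  assert_spike_table(spikes)
  onsets <- protocol$train_onsets
  stim_times <- protocol$events$time_s
  duration <- max(spikes$time_s, stim_times) + 2
  out <- withr_seed(seed, {
    if (kind == "time_shift") {
      if (diff(shift_range) < 0 || any(shift_range < 0)) {
        abort("`shift_range` must be a non-negative increasing range.")
      }
      trial <- pmax(findInterval(spikes$time_s, onsets), 1L)
      cell_i <- match(spikes$cell_id, unique(spikes$cell_id))
      key <- paste(cell_i, trial)
      ukey <- unique(key)
      shift <- setNames(runif(length(ukey), shift_range[1], shift_range[2]), ukey)
      sp <- spikes
      sp$time_s <- sp$time_s + unname(shift[key])
      sp <- dplyr::arrange(sp, .data$cell_id, .data$time_s)
      list(spikes = sp, train_onsets = onsets)
    } else if (kind == "no_stim_random") {
      lo <- -window[1]; hi <- duration - window[2]
      found <- numeric(0)
      for (it in seq_len(20000)) {
        if (length(found) >= n_trials) break
        t0 <- runif(1, lo, hi)
        if (!any(stim_times >= t0 + window[1] & stim_times < t0 + window[2])) {
          found <- c(found, t0)
        }
      }
      if (length(found) < n_trials) {
        abort("Could not place the requested number of stimulus-free windows.")
      }
      list(spikes = spikes, train_onsets = sort(found))
    } else {
      last_stim <- protocol$events |>
        group_by(.data$train_id) |>
        summarise(t = max(.data$time_s), .groups = "drop")
      list(spikes = spikes, train_onsets = last_stim$t + 2)
    }
  })
  out$kind <- kind
  out
}

#' Remove spikes in a blanking window after each stimulus
#'
#' Deletes every spike with time in `[stimulus, stimulus + blank_ms)` for every
#' stimulus of the protocol; all other spikes are untouched.
#'
#' @param spikes A spike table.
#' @param protocol The realised [stim_protocol()].
#' @param blank_ms Blanking window, ms.
#' @return The filtered spike table.
#' @export
remove_post_stimulus_spikes <- function(spikes, protocol, blank_ms = 50) {
  assert_spike_table(spikes)
  stim <- sort(protocol$events$time_s)
  idx <- findInterval(spikes$time_s, stim)
  rel <- ifelse(idx >= 1, (spikes$time_s - stim[pmax(idx, 1)]) * 1000, Inf)
  keep <- !(rel >= 0 & rel < blank_ms)
  spikes[keep, , drop = FALSE]
}
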