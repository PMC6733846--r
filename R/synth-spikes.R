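#' Specify a synthetic evoked spiking population
#'
#' Cells are inhomogeneous-Poisson units whose rate is a constant baseline plus
#' stimulus-locked response kernels. Four response archetypes are supported,
#' mirroring the taxonomy seen in somatosensory cortex and dorsolateral
#' striatum under cutaneous forelimb stimulation: a short-latency excitation;
#' an excitation followed by a pause and a rebound; a pause followed by a late
#' excitation (100-300 ms); and a pause only. Response latencies are drawn from
#' a log-normal distribution parameterised by its median.
#'
#' Two population structures are available. `"stereotyped"` (S1-like): every
#' stimulus of a train evokes the same per-cell response. `"sequential"`
#' (DLS-like): each cell carries a preferred phase drawn uniformly over one
#' inter-stimulus cycle (shifting its response within the cycle) and a
#' stimulus-index gain profile concentrated on one stimulus, so successive
#' stimuli evoke distinct population patterns.
#'
#' @param n_cells Number of cells.
#' @param structure `"stereotyped"` or `"sequential"`.
#' @param baseline_rate Baseline firing rate, Hz.
#' @param latency_median_ms Median of the log-normal response-latency
#'   distribution, ms.
#' @param latency_sdlog Log-scale SD of the latency distribution
#'   (dimensionless); larger values broaden the distribution at fixed median.
#' @param archetype_mix Named probability vector over the four archetypes;
#'   must sum to 1.
#' @param gain Mean number of evoked spikes per stimulus per cell
#'   (dimensionless rate multiplier on the unit-integral kernels).
#' @param peak_jitter_ms SD (ms) of the trial-to-trial jitter of the response
#'   kernel position.
#' @param pause_depth Fractional suppression of baseline during pause windows,
#'   in `[0, 1]`.
#' @param sequential_concentration Dirichlet boost added to a cell's preferred
#'   stimulus index when drawing sequential gain profiles.
#' @param region Region label written into spike tables; defaults to `"DLS"`
#'   for sequential and `"S1"` for stereotyped populations.
#' @param seed Default seed used by [generate_population_spikes()].
#'
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_cells = 100,
                            structure = c("sequential", "stereotyped"),
                            baseline_rate = 5,
                            latency_median_ms = 19,
                            latency_sdlog = 0.4,
                            archetype_mix = c(short_excitation = 0.4,
                                              excitation_pause_rebound = 0.25,
                                              pause_late_excitation = 0.2,
                                              pause_only = 0.15),
                            gain = 2,
                            peak_jitter_ms = 2,
                            pause_depth = 0.8,
                            sequential_concentration = 6,
                            region = NULL,
                            seed = 1L) {
  structure_ <- match.arg(structure)
  check_positive(n_cells, "n_cells")
  check_positive(baseline_rate, "baseline_rate")
  check_positive(latency_median_ms, "latency_median_ms")
  check_positive(gain, "gain", strict = FALSE)
  check_positive(peak_jitter_ms, "peak_jitter_ms", strict = FALSE)
  kinds <- c("short_excitation", "excitation_pause_rebound",
             "pause_late_excitation", "pause_only")
  if (!setequal(names(archetype_mix), kinds)) {
    abort("`archetype_mix` must be named with the four response archetypes.")
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8 || any(archetype_mix < 0)) {
    abort("`archetype_mix` must be a probability vector summing to 1.")
  }
  if (pause_depth < 0 || pause_depth > 1) abort("`pause_depth` must lie in [0, 1].")
  structure(
    list(
      n_cells = as.integer(n_cells),
      structure = structure_,
      baseline_rate = baseline_rate,
      latency_median_ms = latency_median_ms,
      latency_sdlog = latency_sdlog,
      archetype_mix = archetype_mix[kinds],
      gain = gain,
      peak_jitter_ms = peak_jitter_ms,
      pause_depth = pause_depth,
      sequential_concentration = sequential_concentration,
      region = region %||% if (structure_ == "sequential") "DLS" else "S1",
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

# Unit-integral difference-of-exponentials kernel (per-ms density).
# rise/decay in ms; integral over s >= 0 equals 1.
alpha_kernel <- function(s, rise = 2, decay = 10) {
  out <- (exp(-s / decay) - exp(-s / rise)) / (decay - rise)
  out[s < 0] <- 0
  out
}

# Inverse-CDF sampler for alpha_kernel on a 0.1-ms grid.
sample_alpha_kernel <- function(n, rise = 2, decay = 10) {
  if (n == 0) return(numeric(0))
  s <- seq(0, decay * 8, by = 0.1)
  cdf <- cumsum(alpha_kernel(s, rise, decay)) * 0.1
  cdf <- cdf / max(cdf)
  approx(cdf, s, xout = runif(n), rule = 2)$y
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Draw per-cell response parameters for a population
#'
#' Realises the random per-cell attributes implied by a [population_spec()]:
#' archetype, response latency, preferred phase (sequential populations only),
#' stimulus-index gain profile, and the archetype's kernel geometry (excitation
#' onsets, pause window).
#'
#' @param pop A [population_spec()].
#' @param protocol A realised [stim_protocol()] (sets the inter-stimulus cycle
#'   and the number of stimulus-gain entries).
#' @param seed Integer seed.
#' @return A tibble with one row per cell. `gain_profile` is a list-column of
#'   length-`n_stimuli` multipliers with mean 1.
#' @export
draw_population_cells <- function(pop, protocol, seed = pop$seed) {
  if (!inherits(pop, "population_spec")) abort("`pop` must be a `population_spec`.")
  n <- pop$n_cells
  k <- protocol$n_stimuli
  cycle_ms <- 1000 / protocol$train_rate
  withr_seed(seed, {
    archetype <- sample(names(pop$archetype_mix), n, replace = TRUE,
                        prob = pop$archetype_mix)
    latency <- rlnorm(n, meanlog = log(pop$latency_median_ms),
                      sdlog = pop$latency_sdlog)
    phase <- if (pop$structure == "sequential") runif(n, 0, cycle_ms) else rep(0, n)
    preferred <- sample.int(k, n, replace = TRUE)
    gain_profile <- lapply(seq_len(n), function(i) {
      if (pop$structure == "stereotyped") {
        rep(1, k)
      } else {
        alpha <- rep(0.3, k)
        alpha[preferred[i]] <- alpha[preferred[i]] + pop$sequential_concentration
        rdirichlet1(alpha) * k
      }
    })
    has_exc1 <- archetype %in% c("short_excitation", "excitation_pause_rebound")
    has_pause <- archetype != "short_excitation"
    pause_start <- dplyr::case_when(
      archetype == "excitation_pause_rebound" ~ latency + 12,
      archetype == "pause_late_excitation" ~ latency,
      archetype == "pause_only" ~ latency,
      TRUE ~ NA_real_
    )
    pause_end <- dplyr::case_when(
      archetype == "excitation_pause_rebound" ~ pause_start + 50,
      archetype == "pause_late_excitation" ~ 100,
      archetype == "pause_only" ~ latency + 80,
      TRUE ~ NA_real_
    )
    exc2_onset <- dplyr::case_when(
      archetype == "excitation_pause_rebound" ~ pause_end + 5,
      archetype == "pause_late_excitation" ~ runif(n, 110, 240),
      TRUE ~ NA_real_
    )
    tibble(
      cell_id = sprintf("c%04d", seq_len(n)),
      region = pop$region,
      archetype = archetype,
      latency_ms = latency,
      phase_ms = phase,
      preferred_stimulus = preferred,
      gain = pop$gain,
      gain_profile = gain_profile,
      exc1_onset = ifelse(has_exc1, latency, NA_real_) + phase,
      pause_start = pause_start + ifelse(has_pause, phase, NA_real_),
      pause_end = pause_end + ifelse(has_pause, phase, NA_real_),
      exc2_onset = exc2_onset + phase,
      exc2_gain = ifelse(archetype == "excitation_pause_rebound", 0.7,
                         ifelse(archetype == "pause_late_excitation", 1, NA_real_))
    )
  })
}

#' Evaluate a population's noiseless evoked rate function
#'
#' Returns the per-cell firing rate (Hz) at times relative to a single
#' stimulus, i.e. the intensity function that [generate_population_spikes()]
#' realises with Poisson sampling (before trial-to-trial jitter). Intended as a
#' ground-truth oracle: the rate is non-negative by construction.
#'
#' @param cells A tibble from [draw_population_cells()], or a subset of rows.
#' @param t_ms Numeric vector of times since stimulus onset, ms.
#' @param stim_index Which stimulus of the train (indexes the gain profile).
#' @param baseline_rate Baseline rate, Hz.
#' @param pause_depth Fractional pause suppression.
#' @return A matrix `nrow(cells)` x `length(t_ms)` of rates in Hz.
#' @export
evoked_rate <- function(cells, t_ms, stim_index = 1, baseline_rate = 5,
                        pause_depth = 0.8) {
  out <- matrix(baseline_rate, nrow(cells), length(t_ms))
  for (i in seq_len(nrow(cells))) {
    g <- cells$gain_profile[[i]][stim_index] * cells$gain[i]
    r <- rep(baseline_rate, length(t_ms))
    if (!is.na(cells$pause_start[i])) {
      inpause <- t_ms >= cells$pause_start[i] & t_ms < cells$pause_end[i]
      r[inpause] <- r[inpause] * (1 - pause_depth)
    }
    if (!is.na(cells$exc1_onset[i])) {
      r <- r + 1000 * g * alpha_kernel(t_ms - cells$exc1_onset[i])
    }
    if (!is.na(cells$exc2_onset[i])) {
      r <- r + 1000 * g * cells$exc2_gain[i] * alpha_kernel(t_ms - cells$exc2_onset[i])
    }
    out[i, ] <- r
  }
  out
}

#' Simulate spike trains for a population under a stimulation protocol
#'
#' Spikes are drawn from the inhomogeneous-Poisson intensity
#' `baseline * (1 - pause) + evoked kernels` exactly: baseline spikes are
#' homogeneous Poisson, thinned inside each cell's pause window after every
#' stimulus, and evoked spikes are added per stimulus with Poisson counts and
#' kernel-distributed times, jittered trial-to-trial by `peak_jitter_ms`.
#'
#' @param pop A [population_spec()].
#' @param protocol A realised [stim_protocol()].
#' @param duration Session duration, s. Defaults to covering all protocol
#'   events plus 2 s. Must be positive and cover the protocol.
#' @param seed Integer seed (defaults to the spec's seed).
#' @param cells Optional pre-drawn cell table from [draw_population_cells()];
#'   when supplied only the spiking realisation is random.
#'
#' @return A spike table: tibble with `cell_id`, `time_s` (sorted within cell),
#'   `region`, plus attributes `cells` (the per-cell parameter table) and
#'   `spec`.
#' @export
generate_population_spikes <- function(pop, protocol, duration = NULL,
                                       seed = pop$seed, cells = NULL) {
  if (is.null(protocol$events)) abort("Protocol has no event times; call generate_protocol().")
  duration <- duration %||% protocol_duration(protocol)
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be positive.")
  if (duration < max(protocol$events$time_s)) {
    abort("`duration` must cover all protocol events.")
  }
  if (is.null(cells)) cells <- draw_population_cells(pop, protocol, seed = seed)
  stim_times <- sort(protocol$events$time_s)
  stim_index <- protocol$events$stim_index[order(protocol$events$time_s)]
  n_ev <- length(stim_times)

  withr_seed(seed + 1L, {
    per_cell <- lapply(seq_len(nrow(cells)), function(i) {
      ci <- cells[i, ]
      # baseline
      nb <- rpois(1, pop$baseline_rate * duration)
      tb <- runif(nb, 0, duration)
      # pause thinning
      if (!is.na(ci$pause_start)) {
        idx <- findInterval(tb, stim_times)
        rel <- ifelse(idx >= 1, (tb - stim_times[pmax(idx, 1)]) * 1000, Inf)
        inpause <- rel >= ci$pause_start & rel < ci$pause_end
        drop <- inpause & runif(nb) < pop$pause_depth
        tb <- tb[!drop]
      }
      # evoked components
      tev <- numeric(0)
      g_ev <- ci$gain_profile[[1]][stim_index] * ci$gain
      jit <- rnorm(n_ev, 0, pop$peak_jitter_ms)
      for (comp in c("exc1", "exc2")) {
        onset <- ci[[paste0(comp, "_onset")]]
        if (is.na(onset)) next
        rel_gain <- if (comp == "exc1") 1 else ci$exc2_gain
        counts <- rpois(n_ev, g_ev * rel_gain)
        if (sum(counts) == 0) next
        base_t <- rep(stim_times, counts)
        base_j <- rep(jit, counts)
        offs <- sample_alpha_kernel(sum(counts))
        tev <- c(tev, base_t + (onset + base_j + offs) / 1000)
      }
      tt <- sort(c(tb, tev))
      tt <- tt[tt >= 0 & tt <= duration]
      tibble(cell_id = ci$cell_id, time_s = tt, region = ci$region)
    })
    out <- dplyr::bind_rows(per_cell)
    attr(out, "cells") <- cells
    attr(out, "spec") <- pop
    out
  })
}
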