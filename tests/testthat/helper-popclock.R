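# small shared fixtures, built in code

tiny_protocol <- function(n_trains = 2, n_stimuli = 3, rate = 2, seed = 1) {
  generate_protocol(stim_protocol(n_trains = n_trains, n_stimuli = n_stimuli,
                                  train_rate = rate), seed = seed)
}

# deterministic spike table: one spike per listed time
spike_tbl <- function(times, cell = "c1", region = "DLS") {
  tibble::tibble(cell_id = cell, time_s = times, region = region)
}

# a single-stimulus protocol matching the latency-analysis conditions
single_stim_protocol <- function(n = 250, seed = 2) {
  generate_protocol(stim_protocol(n_trains = n, n_stimuli = 1,
                                  inter_train_interval = c(5, 5)), seed = seed)
}

pure_excitation_mix <- c(short_excitation = 1, excitation_pause_rebound = 0,
                         pause_late_excitation = 0, pause_only = 0)

# shared heavyweight objects for the acceptance criteria, built once per run
acceptance_env <- new.env(parent = emptyenv())

acceptance_fixtures <- function() {
  if (!is.null(acceptance_env$ready)) return(acceptance_env)
  pr <- generate_protocol(stim_protocol(), seed = 2)
  seq_pop <- population_spec(n_cells = 200, structure = "sequential", seed = 3)
  ste_pop <- population_spec(n_cells = 200, structure = "stereotyped", seed = 3)
  acceptance_env$protocol <- pr
  acceptance_env$spikes_seq <- generate_population_spikes(seq_pop, pr)
  acceptance_env$spikes_ste <- generate_population_spikes(ste_pop, pr)
  acceptance_env$pv_seq <- bin_population(acceptance_env$spikes_seq, pr)
  acceptance_env$pv_ste <- bin_population(acceptance_env$spikes_ste, pr)
  acceptance_env$sizes <- c(10, 100, 200)
  acceptance_env$curve_seq <- population_size_curve(
    acceptance_env$pv_seq, sizes = acceptance_env$sizes, n_repeats = 50,
    seed = 11, condition = "sequential")
  acceptance_env$ready <- TRUE
  acceptance_env
}
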