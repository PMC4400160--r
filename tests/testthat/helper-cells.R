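# Simulate one model neuron and return its metrics and label; reduced IPI
# sets keep unit tests fast while preserving the IPIs the summary statistics
# need (3 ms, one in 35-75 ms, and 75 ms).
sim_cell <- function(e, ratio, delay, n_trials = 10, seed = 1,
                     noise = noise_spec(), ipis = default_ipis(), ...) {
  syn <- synapse_params(e, ie_ratio = ratio, ie_delay = delay, ...)
  simulate_trial_set(syn, neuron_params(), noise, ipis = ipis,
                     n_trials = n_trials, base_seed = seed)
}

cell_label <- function(e, ratio, delay, seed = 1, n_trials = 10, ...) {
  classify(compute_metrics(sim_cell(e, ratio, delay, n_trials = n_trials,
                                    seed = seed, ...)))$label
}

# Majority label across seeds for stochastic region checks.
majority_label <- function(e, ratio, delay, seeds = 1:5, ...) {
  labs <- vapply(seeds, function(s) cell_label(e, ratio, delay, seed = s, ...),
                 character(1))
  names(sort(table(labs), decreasing = TRUE))[1]
}

# Build a trial_set directly from spike times for metric unit tests.
toy_trial_set <- function(cond_spikes, ipis, n_trials, onset = 200,
                          duration = 500, spont_rate = NULL, spont_sd = NULL,
                          tone_spikes = NULL) {
  spikes <- list(); stims <- list()
  for (k in seq_along(ipis)) {
    nm <- paste0("ipi_", ipis[k])
    spikes[[nm]] <- cond_spikes[[k]]
    stims[[nm]] <- stimulus_spec("pulse_train", ipi = ipis[k],
                                 duration = duration, onset = onset)
  }
  if (!is.null(tone_spikes)) {
    spikes[["tone"]] <- tone_spikes
    stims[["tone"]] <- stimulus_spec("pure_tone", onset = onset)
  }
  trial_set(spikes, stims, spont_rate = spont_rate, spont_sd = spont_sd)
}
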