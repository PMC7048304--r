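# Canonical short-term-depression configurations (tau_pE = 0.15 s,
# tau_pI = 0.10 s). The amplitude pairing follows the mechanism: strong
# depression of excitation gives the negative slope.
canonical_sync_plus <- function()
  plasticity_params("depression", A_DE = 0.1, A_DI = 0.4)
canonical_sync_minus <- function()
  plasticity_params("depression", A_DE = 0.4, A_DI = 0.1)

# run the full 8-48 Hz protocol over several seeds and collect rho/p/label
protocol_over_seeds <- function(plasticity, seeds, neuron = neuron_params(),
                                trials = 10, rates = seq(8, 48, by = 4),
                                keep_spikes = FALSE) {
  rows <- lapply(seeds, function(s) {
    fn <- simulate_neuron(neuron, plasticity, rates = rates, trials = trials,
                          seed = s, keep_spikes = keep_spikes)
    data.frame(seed = s, rho = fn$rho, p = fn$p, label = fn$label,
               onset = if (keep_spikes) onset_rate(fn) else NA_real_)
  })
  do.call(rbind, rows)
}

# deterministic synthetic raster: n_trials trials, `counts[k]` spikes in the
# window of event k, each spike at the event time + latency + small offset
synthetic_raster <- function(train, counts, n_trials = 20, latency = 10) {
  lapply(seq_len(n_trials), function(i) {
    unlist(lapply(seq_along(train$events), function(k) {
      n <- counts[k]
      if (n == 0) return(numeric(0))
      train$events[k] + latency + seq_len(n)
    }))
  })
}
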