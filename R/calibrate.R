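#' Measure the spontaneous firing rate of the unstimulated neuron
#'
#' Simulates silence (no synaptic drive) for `duration_s` seconds and counts
#' threshold crossings, averaging over seeds. This isolates the
#' noise-driven firing that sets the model's spontaneous rate (~4 spk/s at
#' the default noise scale).
#'
#' @param neuron a [neuron_params()] object.
#' @param duration_s simulated silence per seed (s).
#' @param seeds integer vector of seeds.
#' @return Mean spontaneous rate (spk/s) across seeds.
#' @export
spontaneous_rate <- function(neuron = neuron_params(), duration_s = 10,
                             seeds = 1:5) {
  silent <- structure(list(rate = 1, duration = duration_s * 1000, pre = 0,
                           post = 0, events = numeric(0), jitter_sd = 0,
                           label = "silence"), class = "stimulus_train")
  rates <- vapply(seeds, function(s) {
    tr <- simulate_trial(silent, neuron, plasticity_params(), seed = s,
                         keep_trace = FALSE)
    length(tr$spikes) / duration_s
  }, numeric(1))
  mean(rates)
}

#' Calibrate the membrane noise scale to a target spontaneous rate
#'
#' Sweeps `sigma_grid`, measures the spontaneous rate at each value with
#' [spontaneous_rate()], and returns the grid results plus the scale whose
#' measured rate is closest to `target` (with linear interpolation between
#' the two bracketing grid points when possible).
#'
#' @param target target spontaneous rate (spk/s).
#' @param sigma_grid candidate noise scales (mV/sqrt(ms)).
#' @param neuron base [neuron_params()] (its `sigma_noise` is overridden).
#' @param duration_s,seeds passed to [spontaneous_rate()].
#' @return A list with `sigma` (recommended scale) and `grid` (data frame
#'   of scale vs measured rate).
#' @export
calibrate_noise <- function(target = 4, sigma_grid = seq(1.4, 3.2, by = 0.2),
                            neuron = neuron_params(), duration_s = 10,
                            seeds = 1:5) {
  rates <- vapply(sigma_grid, function(s) {
    np <- neuron
    np$sigma_noise <- s
    spontaneous_rate(np, duration_s, seeds)
  }, numeric(1))
  grid <- data.frame(sigma_noise = sigma_grid, rate = rates)
  sigma <- if (any(rates >= target) && any(rates <= target)) {
    stats::approx(rates, sigma_grid, xout = target, ties = mean)$y
  } else sigma_grid[which.min(abs(rates - target))]
  list(sigma = sigma, grid = grid)
}

#' Measure the onset response of a canonical configuration
#'
#' Runs the protocol and returns the firing rate in the first post-onset
#' analysis window averaged across rates and seeds (see [onset_rate()]).
#' The synaptic amplitude defaults are calibrated so this lies in the
#' 40-60 spk/s band for the canonical Sync+/Sync- configurations.
#'
#' @param neuron,plasticity model configuration.
#' @param rates,trials protocol settings.
#' @param seeds integer vector of protocol seeds.
#' @return Mean onset rate (spk/s).
#' @export
onset_response <- function(neuron = neuron_params(),
                           plasticity = plasticity_params(),
                           rates = seq(8, 48, by = 4), trials = 10,
                           seeds = 1:3) {
  mean(vapply(seeds, function(s) {
    fn <- simulate_neuron(neuron, plasticity, rates = rates, trials = trials,
                          seed = s)
    onset_rate(fn)
  }, numeric(1)))
}
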