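#' Alpha-function synaptic conductance kernel
#'
#' The conductance waveform of a single synaptic input,
#' `g(t) = A * (t/tau_s) * exp(1 - t/tau_s)` for `t >= 0` and 0 for `t < 0`
#' (causal). The kernel is peak-normalized: it vanishes at onset, rises to
#' its single maximum `A` at `t = tau_s`, and decays exponentially, so the
#' amplitude parameter is directly the peak conductance in nS and comparable
#' to the 0-6 nS (excitatory) / 0-12 nS (inhibitory) per-synapse ranges.
#'
#' @param t time since kernel onset (ms); vectorized. Negative times return 0.
#' @param amplitude peak conductance (nS).
#' @param tau_s time constant (ms), `> 0`.
#' @return Conductance values (nS), same length as `t`.
#' @examples
#' alpha_kernel(5, 5, 5)  # peak: returns 5
#' alpha_kernel(0, 5, 5)  # 0 at onset
#' @export
alpha_kernel <- function(t, amplitude, tau_s = 5) {
  if (tau_s <= 0) stop("tau_s must be > 0")
  ifelse(t >= 0, amplitude * (t / tau_s) * exp(1 - t / tau_s), 0)
}

# Kernel sampled at the integration grid, truncated where it has decayed to
# < 1e-4 of peak (12 time constants).
sampled_alpha_kernel <- function(tau_s, dt) {
  tt <- seq(dt, 12 * tau_s, by = dt)
  (tt / tau_s) * exp(1 - tt / tau_s)
}

#' Pooled synaptic conductance traces for a stimulus train
#'
#' For each acoustic event, `n_syn` excitatory alpha kernels are placed at
#' `event + syn_delay + jitter` and `n_syn` inhibitory kernels additionally
#' lagged by the I-E delay, each jittered independently (Gaussian, sd
#' `jitter_syn` ms). Kernel peak amplitudes are the per-synapse base
#' amplitudes scaled by the event's release probability. The returned traces
#' are the sums over all kernels, sampled at `dt` over the whole trial
#' (pre + stimulus + post).
#'
#' Jitter draws come from R's RNG stream (two blocks: all excitatory
#' synapses, then all inhibitory synapses, event-major order).
#'
#' @param train a [pulse_train()] object.
#' @param neuron a [neuron_params()] object.
#' @param release_E,release_I per-event release probabilities (recycled if
#'   length 1); defaults 1 (no plasticity).
#' @return A list with `g_e`, `g_i` (nS, length `n_steps`), `times` (ms) and
#'   `n_steps`.
#' @export
conductance_traces <- function(train, neuron, release_E = 1, release_I = 1) {
  stopifnot(inherits(train, "stimulus_train"), inherits(neuron, "neuron_params"))
  total <- train$pre + train$duration + train$post
  n <- round(total / neuron$dt)
  n_ev <- length(train$events)
  if (n_ev == 0)
    return(list(g_e = numeric(n), g_i = numeric(n),
                times = seq_len(n) * neuron$dt, n_steps = n))
  if (any(train$events < 0) || any(train$events >= train$duration + train$post))
    stop("events outside the simulated window")
  release_E <- rep_len(release_E, n_ev)
  release_I <- rep_len(release_I, n_ev)

  kern <- sampled_alpha_kernel(neuron$tau_s, neuron$dt)
  abs_ev <- train$pre + train$events
  ns <- neuron$n_syn

  jit_e <- rnorm(n_ev * ns, 0, neuron$jitter_syn)
  jit_i <- rnorm(n_ev * ns, 0, neuron$jitter_syn)
  onsets_e <- rep(abs_ev, each = ns) + neuron$syn_delay + jit_e
  onsets_i <- rep(abs_ev, each = ns) + neuron$syn_delay + neuron$ie_delay + jit_i
  amps_e <- rep(neuron$A_E * release_E, each = ns)
  amps_i <- rep(neuron$A_I * release_I, each = ns)

  g_e <- add_kernels(numeric(n), kern, onsets_e, amps_e, neuron$dt)
  g_i <- add_kernels(numeric(n), kern, onsets_i, amps_i, neuron$dt)
  list(g_e = g_e, g_i = g_i, times = seq_len(n) * neuron$dt, n_steps = n)
}
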