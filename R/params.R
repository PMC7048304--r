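#' Biophysical parameters of the model neuron
#'
#' Constructs the fixed biophysics of the conductance-based leaky
#' integrate-and-fire neuron: membrane capacitance and leak, synaptic reversal
#' potentials, threshold/reset voltages, the alpha-function synapse time
#' constant, conduction delays, integration step, noise scale, and the pooled
#' synaptic drive per acoustic pulse (number of synapses, per-synapse peak
#' amplitudes, within-pool temporal jitter).
#'
#' Each acoustic pulse is delivered as `n_syn` excitatory and `n_syn`
#' inhibitory alpha-function synapses. Excitatory synapses arrive
#' `syn_delay` ms after the pulse; inhibitory synapses lag excitation by a
#' further `ie_delay` ms. Each synapse in the pool is independently jittered
#' (Gaussian, sd `jitter_syn` ms). With the leak values below the passive
#' membrane time constant is `C/g_rest` = 10 ms.
#'
#' `A_E` and `A_I` are per-synapse *peak* conductances (the alpha kernel is
#' peak-normalized), so the pooled peak drive is about `n_syn * A_E` nS.
#' Defaults are calibrated so that the onset response of the canonical
#' configurations falls in the 40-60 spikes/s range; `sigma_noise` is
#' calibrated so that the unstimulated neuron fires spontaneously at about
#' 4 spikes/s (see [calibrate_noise()]).
#'
#' @param C membrane capacitance (nF).
#' @param g_rest leak conductance (nS).
#' @param E_e,E_i excitatory / inhibitory reversal potentials (mV).
#' @param E_rest resting and post-spike reset potential (mV).
#' @param V_th spike threshold (mV).
#' @param tau_s alpha-function time constant (ms).
#' @param syn_delay synaptic input delay from acoustic pulse to excitatory
#'   conductance onset (ms).
#' @param ie_delay additional lag of inhibition behind excitation (ms).
#' @param dt integration timestep (ms).
#' @param sigma_noise scale of the per-step additive membrane voltage noise
#'   (mV per sqrt(ms); the per-step sd is `sigma_noise * sqrt(dt)`).
#' @param A_E,A_I per-synapse peak conductance of excitatory / inhibitory
#'   inputs (nS). Biologically plausible ranges are 0-6 nS (excitation) and
#'   0-12 nS (inhibition); values outside these produce a warning.
#' @param n_syn number of synapses of each class pooled per acoustic pulse.
#' @param jitter_syn within-pool Gaussian temporal jitter sd (ms).
#'
#' @return An object of class `"neuron_params"` (a validated named list).
#' @seealso [plasticity_params()], [simulate_neuron()]
#' @examples
#' np <- neuron_params()
#' np$C / np$g_rest * 1000  # membrane time constant, ms
#' @export
neuron_params <- function(C = 0.25, g_rest = 25, E_e = 0, E_i = -85,
                          E_rest = -65, V_th = -50, tau_s = 5,
                          syn_delay = 10, ie_delay = 5, dt = 0.1,
                          sigma_noise = 2.8, A_E = 3.5, A_I = 6.6,
                          n_syn = 10, jitter_syn = 1) {
  p <- list(C = C, g_rest = g_rest, E_e = E_e, E_i = E_i, E_rest = E_rest,
            V_th = V_th, tau_s = tau_s, syn_delay = syn_delay,
            ie_delay = ie_delay, dt = dt, sigma_noise = sigma_noise,
            A_E = A_E, A_I = A_I, n_syn = n_syn, jitter_syn = jitter_syn)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron parameter '", nm, "' must be a single finite number")
  }
  if (C <= 0) stop("C must be > 0")
  if (g_rest <= 0) stop("g_rest must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (!(E_i < E_rest && E_rest < E_e))
    stop("reversal potentials must satisfy E_i < E_rest < E_e")
  if (V_th <= E_rest) stop("V_th must exceed E_rest")
  if (A_E < 0 || A_I < 0) stop("synaptic amplitudes must be >= 0")
  if (A_E > 6) warning("A_E = ", A_E, " nS is outside the plausible 0-6 nS range")
  if (A_I > 12) warning("A_I = ", A_I, " nS is outside the plausible 0-12 nS range")
  if (n_syn < 1 || n_syn != round(n_syn)) stop("n_syn must be a positive integer")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (jitter_syn < 0) stop("jitter_syn must be >= 0")
  structure(p, class = "neuron_params")
}

#' Short-term plasticity and spike-frequency adaptation parameters
#'
#' Presynaptic release probability `P_rel` is a per-synapse-class dynamic
#' variable: immediately after each acoustic pulse it is multiplied by
#' `(1 - A_D)` and between pulses it relaxes exponentially back to its
#' baseline `P_0` with time constant `tau_p` (seconds). A pulse's conductance
#' amplitude is the base amplitude scaled by the release probability in
#' effect at that pulse. Positive `A_D` gives short-term depression (STD),
#' negative `A_D` short-term facilitation (STF, capped at `P_rel = 1`).
#'
#' The `mode` selects baselines per class: depression uses `P_0 = 1` on both
#' classes; facilitation uses `P_0 = 0.5` on both (so that facilitated
#' conductance amplitudes stay comparable to the depressed ones); `"mixed"`
#' depresses excitation (`P_0 = 1`) while facilitating inhibition
#' (`P_0 = 0.5`). Explicit `P0_E`/`P0_I` override the mode defaults.
#'
#' Spike-frequency adaptation (SFA) is a postsynaptic, spike-triggered
#' potassium-like conductance: every output spike increments `g_sra` by
#' `delta_g_sra`, and `g_sra` relaxes to zero with time constant `tau_sra`,
#' hyperpolarizing the neuron toward `E_K`. `delta_g_sra = 0` disables SFA.
#'
#' @param mode plasticity mode: `"none"`, `"depression"`, `"facilitation"`,
#'   or `"mixed"` (depression of excitation, facilitation of inhibition).
#' @param A_DE,A_DI adaptation amplitudes for excitatory / inhibitory
#'   synapses, in `[-0.5, 0.5]`; positive depresses, negative facilitates.
#' @param tau_pE,tau_pI recovery time constants (s), naturalistic range
#'   0.05-0.2 s.
#' @param P0_E,P0_I baseline release probabilities in `(0, 1]`; `NULL` means
#'   use the mode default.
#' @param delta_g_sra SFA conductance increment per spike (nS); 0 disables.
#' @param tau_sra SFA decay time constant (ms).
#' @param E_K SFA (potassium) reversal potential (mV).
#'
#' @return An object of class `"plasticity_params"`.
#' @seealso [release_trace()], [simulate_neuron()]
#' @examples
#' plasticity_params("depression", A_DE = 0.1, A_DI = 0.4)
#' plasticity_params("mixed", A_DE = 0.3, A_DI = -0.4)
#' @export
plasticity_params <- function(mode = c("none", "depression", "facilitation", "mixed"),
                              A_DE = 0, A_DI = 0,
                              tau_pE = 0.15, tau_pI = 0.10,
                              P0_E = NULL, P0_I = NULL,
                              delta_g_sra = 0, tau_sra = 50, E_K = -85) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    none         = c(1, 1),
    depression   = c(1, 1),
    facilitation = c(0.5, 0.5),
    mixed        = c(1, 0.5))
  if (is.null(P0_E)) P0_E <- defaults[1]
  if (is.null(P0_I)) P0_I <- defaults[2]
  if (mode == "none" && (A_DE != 0 || A_DI != 0))
    stop("mode 'none' requires A_DE = A_DI = 0")
  for (a in c(A_DE, A_DI))
    if (abs(a) > 0.5) stop("adaptation amplitudes must lie in [-0.5, 0.5]")
  if (mode == "depression" && (A_DE < 0 || A_DI < 0))
    stop("depression mode requires A_DE, A_DI >= 0")
  if (mode == "facilitation" && (A_DE > 0 || A_DI > 0))
    stop("facilitation mode requires A_DE, A_DI <= 0")
  if (mode == "mixed" && (A_DE < 0 || A_DI > 0))
    stop("mixed mode requires A_DE >= 0 (depression) and A_DI <= 0 (facilitation)")
  if (tau_pE <= 0 || tau_pI <= 0) stop("recovery time constants must be > 0")
  for (p0 in c(P0_E, P0_I))
    if (p0 <= 0 || p0 > 1) stop("baseline release probability must lie in (0, 1]")
  if (delta_g_sra < 0) stop("delta_g_sra must be >= 0")
  if (tau_sra <= 0) stop("tau_sra must be > 0")
  structure(list(mode = mode, A_DE = A_DE, A_DI = A_DI,
                 tau_pE = tau_pE, tau_pI = tau_pI,
                 P0_E = P0_E, P0_I = P0_I,
                 delta_g_sra = delta_g_sra, tau_sra = tau_sra, E_K = E_K),
            class = "plasticity_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Model neuron parameters\n")
  cat(sprintf("  C = %.3g nF, g_rest = %.3g nS (tau_m = %.3g ms)\n",
              x$C, x$g_rest, 1000 * x$C / x$g_rest))
  cat(sprintf("  E_rest = %g mV, V_th = %g mV, E_e = %g mV, E_i = %g mV\n",
              x$E_rest, x$V_th, x$E_e, x$E_i))
  cat(sprintf("  synapse: tau_s = %g ms, %d E + %d I per pulse, A_E = %g nS, A_I = %g nS\n",
              x$tau_s, x$n_syn, x$n_syn, x$A_E, x$A_I))
  cat(sprintf("  delays: synaptic %g ms, I-E %g ms; jitter sd %g ms\n",
              x$syn_delay, x$ie_delay, x$jitter_syn))
  cat(sprintf("  dt = %g ms, noise scale = %g mV/sqrt(ms)\n", x$dt, x$sigma_noise))
  invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf("Short-term plasticity [%s]\n", x$mode))
  cat(sprintf("  E: A_D = %g, tau_p = %g s, P0 = %g\n", x$A_DE, x$tau_pE, x$P0_E))
  cat(sprintf("  I: A_D = %g, tau_p = %g s, P0 = %g\n", x$A_DI, x$tau_pI, x$P0_I))
  if (x$delta_g_sra > 0)
    cat(sprintf("  SFA: delta_g = %g nS, tau = %g ms, E_K = %g mV\n",
                x$delta_g_sra, x$tau_sra, x$E_K))
  invisible(x)
}
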