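#' Release-probability update at an acoustic pulse
#'
#' Immediately after each stimulus pulse the presynaptic release probability
#' is multiplied by `(1 - A_D)`. Positive `A_D` depresses release; negative
#' `A_D` facilitates it, in which case the result is capped at 1 (a release
#' probability cannot exceed 1).
#'
#' @param p_rel current release probability (> 0).
#' @param A_D adaptation amplitude in `[-0.5, 0.5]`.
#' @return Updated release probability.
#' @examples
#' release_after_pulse(1, 0.4)     # 0.6
#' release_after_pulse(0.5, -0.4)  # 0.7
#' @export
release_after_pulse <- function(p_rel, A_D) {
  if (any(abs(A_D) > 0.5)) stop("A_D must lie in [-0.5, 0.5]")
  if (any(p_rel <= 0)) stop("p_rel must be > 0")
  pmin((1 - A_D) * p_rel, 1)
}

#' Exponential recovery of release probability between pulses
#'
#' In the absence of pulses the release probability relaxes to its baseline
#' `P_0` as `dP/dt = (P_0 - P)/tau_p`. The closed form is used, so recovery
#' over an inter-pulse interval is exact with no per-step integration:
#' `P_0 - (P_0 - p_rel) * exp(-elapsed/tau_p)`.
#'
#' @param p_rel release probability at the start of the interval.
#' @param elapsed elapsed time (s), `>= 0`.
#' @param tau_p recovery time constant (s), `> 0`.
#' @param P0 baseline release probability.
#' @return Release probability after `elapsed` seconds.
#' @examples
#' release_recovery(0.6, 0.125, 0.125, 1)  # 1 - 0.4 * exp(-1)
#' @export
release_recovery <- function(p_rel, elapsed, tau_p, P0 = 1) {
  if (any(elapsed < 0)) stop("elapsed must be >= 0")
  if (tau_p <= 0) stop("tau_p must be > 0")
  P0 - (P0 - p_rel) * exp(-elapsed / tau_p)
}

#' Per-event release probabilities along a pulse train
#'
#' Iterates recovery (closed form over each inter-event interval) and the
#' post-pulse multiplicative update along an ascending event schedule, and
#' returns the release probability *in effect at* each event — the pre-update
#' value, which is what scales that event's conductance amplitude
#' (`A(t) = A(0) * P_rel(t)`): a pulse spends the currently available
#' resources and then depletes (or facilitates) them.
#'
#' For a periodic train the sequence converges geometrically to the fixed
#' point of `p -> P_0 - (P_0 - (1 - A_D) p) * exp(-IPI/tau_p)`.
#'
#' @param events ascending event times (ms).
#' @param A_D adaptation amplitude in `[-0.5, 0.5]`.
#' @param tau_p recovery time constant (s).
#' @param P0 baseline release probability.
#' @return Numeric vector, one release probability per event.
#' @examples
#' ev <- pulse_train(8)$events
#' release_trace(ev, A_D = 0.4, tau_p = 0.1)[2]  # 1 - 0.4 * exp(-1.25)
#' @export
release_trace <- function(events, A_D, tau_p, P0 = 1) {
  if (length(events) == 0) return(numeric(0))
  if (is.unsorted(events, strictly = FALSE)) stop("events must be ascending")
  if (abs(A_D) > 0.5) stop("A_D must lie in [-0.5, 0.5]")
  out <- numeric(length(events))
  p <- P0
  for (k in seq_along(events)) {
    if (k > 1) {
      dt_s <- (events[k] - events[k - 1]) / 1000
      p <- release_recovery(p, dt_s, tau_p, P0)
    }
    out[k] <- p
    p <- release_after_pulse(p, A_D)
  }
  out
}

#' Steady-state release probability of a periodic train
#'
#' Closed-form fixed point of the depression/facilitation map for a periodic
#' train with inter-pulse interval `1/rate`: the pre-update release
#' probability satisfies `p = P_0 - (P_0 - (1 - A_D) p) * exp(-IPI/tau_p)`.
#' Strictly decreasing in `rate` for `A_D > 0`.
#'
#' @param rate repetition rate (Hz).
#' @inheritParams release_trace
#' @return The steady-state (pre-update) release probability.
#' @export
release_steady_state <- function(rate, A_D, tau_p, P0 = 1) {
  if (rate <= 0) stop("rate must be > 0")
  q <- exp(-1 / (rate * tau_p))
  denom <- 1 - (1 - A_D) * q
  p <- if (denom > 0) P0 * (1 - q) / denom else Inf
  if (A_D < 0 && (!is.finite(p) || p < 0 || (1 - A_D) * p > 1)) {
    # facilitation with the cap binding: post-update value pins at 1 and the
    # pre-update steady state is one recovery step from there
    p <- P0 + (1 - P0) * q
  }
  p
}

#' One step of the spike-frequency adaptation conductance
#'
#' The adaptation conductance decays exponentially toward zero with time
#' constant `tau_sra` (exact per-step factor `exp(-dt/tau_sra)`) and is
#' incremented by `delta_g` whenever the neuron fired during the step. This
#' mirrors the update applied inside the compiled integrator.
#'
#' @param g_sra current adaptation conductance (nS, `>= 0`).
#' @param spiked logical; did the neuron fire this step?
#' @param delta_g per-spike increment (nS).
#' @param tau_sra decay time constant (ms).
#' @param dt timestep (ms).
#' @return Updated conductance (nS, never negative).
#' @export
sfa_step <- function(g_sra, spiked, delta_g, tau_sra, dt) {
  if (g_sra < 0) stop("g_sra must be >= 0")
  if (tau_sra <= 0) stop("tau_sra must be > 0")
  if (delta_g < 0) stop("delta_g must be >= 0")
  g_sra * exp(-dt / tau_sra) + if (isTRUE(spiked)) delta_g else 0
}
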