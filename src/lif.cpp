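#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the conductance-based leaky integrate-and-fire
// membrane equation:
//
//   C dV/dt = g_e(t)(E_e - V) + g_i(t)(E_i - V) + g_rest(E_rest - V)
//             + g_sra(t)(E_K - V)
//
// plus per-step additive voltage noise (pre-drawn in R so that all randomness
// flows through R's RNG). Threshold-and-reset spiking: whenever V >= V_th a
// spike time is recorded, V is reset to E_rest, and the spike-frequency
// adaptation conductance g_sra is incremented by delta_g_sra. g_sra decays
// between spikes by the exact per-step factor exp(-dt/tau_sra).
//
// Units: mV, ms, nS; capacitance in pF so that dt * g / C is dimensionless.
//
// [[Rcpp::export]]
List lif_integrate(NumericVector g_e, NumericVector g_i, NumericVector noise,
                   double C_pF, double g_rest, double E_e, double E_i,
                   double E_rest, double V_th, double dt,
                   double delta_g_sra, double tau_sra, double E_K,
                   bool keep_trace, double V0) {
  const int n = g_e.size();
  if (g_i.size() != n || noise.size() != n)
    stop("conductance and noise vectors must have equal length");

  NumericVector V(keep_trace ? n : 0);
  NumericVector g_sra_trace(keep_trace && delta_g_sra > 0 ? n : 0);
  std::vector<double> spikes;
  spikes.reserve(256);

  double v = V0;
  double g_sra = 0.0;
  const double sra_decay = (tau_sra > 0) ? std::exp(-dt / tau_sra) : 0.0;
  const double dt_over_C = dt / C_pF;

  for (int t = 0; t < n; ++t) {
    double I = g_e[t] * (E_e - v) + g_i[t] * (E_i - v) +
               g_rest * (E_rest - v) + g_sra * (E_K - v);
    v += dt_over_C * I + noise[t];
    g_sra *= sra_decay;
    if (!std::isfinite(v))
      stop("membrane potential diverged at step %d (t = %.2f ms)", t + 1,
           (t + 1) * dt);
    if (v >= V_th) {
      spikes.push_back((t + 1) * dt);
      v = E_rest;
      g_sra += delta_g_sra;
    }
    if (keep_trace) {
      V[t] = v;
      if (g_sra_trace.size()) g_sra_trace[t] = g_sra;
    }
  }

  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["V"] = V, _["g_sra"] = g_sra_trace);
}

// Accumulate alpha-function kernels into a conductance trace in place.
// onsets are kernel onset times (ms from trace start), amps the per-kernel
// peak amplitudes (nS). The kernel vector is pre-sampled at dt resolution.
//
// [[Rcpp::export]]
NumericVector add_kernels(NumericVector g, NumericVector kernel,
                          NumericVector onsets, NumericVector amps,
                          double dt) {
  const int n = g.size(), m = kernel.size(), k = onsets.size();
  if (amps.size() != k) stop("onsets and amps must have equal length");
  for (int j = 0; j < k; ++j) {
    int i0 = (int)std::lround(onsets[j] / dt);
    if (i0 < 0) i0 = 0;
    const double a = amps[j];
    for (int i = 0; i < m; ++i) {
      int idx = i0 + i;
      if (idx >= n) break;
      g[idx] += a * kernel[i];
    }
  }
  return g;
}
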