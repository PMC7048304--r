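---
title: "Modelling monotonic rate codes for acoustic flutter with short-term synaptic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling monotonic rate codes for acoustic flutter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flutterlif)
```

## The scientific problem

Neurons in primary auditory cortex represent slowly repeated acoustic events
(acoustic *flutter*, roughly 4–48 Hz) in two complementary ways. Most
stimulus-driven neurons phase-lock to individual pulses (a temporal code).
A sub-population additionally carries a *rate* code: their mean discharge
rate increases (**Sync+**) or decreases (**Sync−**) monotonically with the
repetition rate. `flutterlif` implements a single-compartment,
conductance-based leaky integrate-and-fire (LIF) model of such a neuron and
asks which biophysical mechanism — short-term synaptic depression (STD),
short-term facilitation (STF), or spike-frequency adaptation (SFA) —
suffices to produce both response classes within the flutter range.

## The membrane model

The membrane potential follows

$$C\,\frac{dV}{dt} = g_e(t)\,(E_e - V) + g_i(t)\,(E_i - V)
  + g_{rest}\,(E_{rest} - V) + g_{sra}(t)\,(E_K - V),$$

integrated by forward Euler at `dt = 0.1` ms, with additive Gaussian
voltage noise of standard deviation $\sigma_{noise}\sqrt{dt}$ per step.
When $V \ge V_{th}$ a spike is recorded and $V$ resets to $E_{rest}$; there
is no refractory period beyond the reset. With the default capacitance
(0.25 nF) and leak (25 nS) the passive time constant is 10 ms.

Each acoustic pulse is delivered as 10 excitatory and 10 inhibitory
synapses, each an alpha-function conductance
$g(t) = A\,(t/\tau_s)\,e^{1-t/\tau_s}$ with $\tau_s = 5$ ms, independently
jittered (Gaussian, sd 1 ms). Excitation arrives 10 ms after the pulse;
inhibition lags excitation by a further 5 ms — lagging inhibition is what
confines spiking to a synchronized window per pulse. The kernel is
**peak-normalized** so the amplitude parameters `A_E`, `A_I` read directly
as per-synapse peak conductances in nS, comparable to the plausible 0–6 nS
(excitatory) and 0–12 nS (inhibitory) ranges; the alternative raw
$t\,e^{-t/\tau}$ convention would make the amplitudes
$\tau_s/e$-dependent and harder to interpret.

### Choices where the biophysics is under-determined

* **Threshold and reset.** $V_{th}$ and $E_{rest}$ are not constrained by
  the reference parameter set; we use $E_{rest} = -65$ mV,
  $V_{th} = -50$ mV (typical cortical values) and then calibrate the
  *observable* constraints instead (below). Both are configurable.
* **Noise entry.** Only the resulting spontaneous rate (~4 spk/s) is
  constrained, not whether noise enters as current or voltage. We inject
  per-step Gaussian voltage noise; `calibrate_noise()` sweeps the scale and
  the shipped default (`sigma_noise = 2.8` mV·ms^-1/2^) yields 4.0 spk/s
  over 50 s of simulated silence.
* **Synaptic strengths.** `A_E = 3.5`, `A_I = 6.6` nS (I/E ratio 1.9,
  inside the plausible 1.4–2.0 band) were calibrated once so that the onset
  response of the canonical configurations sits mid-way in the 40–60 spk/s
  reference band (`onset_response()` measures ~48 spk/s); they were fixed
  before any monotonicity comparisons and are not tuned per experiment.

```{r calibration, eval = FALSE}
calibrate_noise(target = 4)$sigma    # ~2.8 at the default biophysics
onset_response(plasticity = plasticity_params("depression",
                                              A_DE = 0.4, A_DI = 0.1))
```

## Short-term plasticity

Release probability is a per-synapse-class resource: immediately after each
acoustic pulse $P_{rel} \to (1 - A_D)\,P_{rel}$, and between pulses it
relaxes to its baseline, $\tau_p\,dP_{rel}/dt = P_0 - P_{rel}$. A pulse's
conductance amplitude is $A(0)\,P_{rel}$ with the **pre-update** value —
the pulse spends the currently available resources, then depletes them
(the Tsodyks–Markram convention). Between events the exact closed form
$P_0 - (P_0 - P)\,e^{-\Delta t/\tau_p}$ is used rather than per-step
integration: it is exact, fast, and its equivalence to a brute-force ODE
integration is enforced by a test at 1e-9 relative tolerance.

Depression ($A_D > 0$, $P_0 = 1$) makes the steady-state release — and so
the per-pulse drive — strictly decreasing in repetition rate:

```{r steady-state}
round(vapply(seq(8, 48, by = 8), release_steady_state, numeric(1),
             A_D = 0.4, tau_p = 0.1), 3)
```

The recovery time constants (0.05–0.2 s) straddle the flutter range: at
8 Hz (125 ms between pulses) recovery is nearly complete and responses are
barely depressed, while at 48 Hz (20.8 ms) depression accumulates. Strong
depression of *excitation* therefore suppresses late pulses at high rates
(Sync−); strong depression of *inhibition* releases them (Sync+).

Facilitation uses $A_D < 0$ with $P_0 = 0.5$ so that conductance
amplitudes remain comparable between modes. Because $P_{rel}$ is a
probability, multiplicative facilitation is **capped at 1**; the cap binds
at high rates and `release_steady_state()` accounts for it. The `"mixed"`
mode (depression of excitation, facilitation of inhibition) covers the
alternative adaptation hypothesis.

SFA is postsynaptic and spike-triggered: each output spike increments a
potassium-like conductance by $\Delta g_{sra}$ (10–50 nS when enabled),
which decays as $\tau_{sra}\,dg_{sra}/dt = -g_{sra}$. Two values are
unconstrained by the reference description and are therefore configurable
defaults, flagged as such: $E_K = -85$ mV (any hyperpolarizing reversal
reproduces the effect) and $\tau_{sra} = 50$ ms. The decay uses the exact
per-step factor $e^{-dt/\tau_{sra}}$ (unconditionally stable and matching
the closed form) rather than the first-order factor $1 - dt/\tau_{sra}$;
at `dt = 0.1` ms the two differ by <1e-6 per step.

## Stimuli

`pulse_train(rate, duration)` places events at $k/\mathrm{rate}$ on the
half-open interval $[0, \mathrm{duration})$ — the first pulse at onset, so
an 8 Hz, 500 ms train has 4 events. Whether a pulse falls exactly at offset
is not observable in any printed quantity; the half-open convention is
fixed here because per-event analyses depend on the count. Trials carry
500 ms pre- and post-stimulus silence; the pre-stimulus window estimates
the spontaneous rate. `jitter_events()` adds Gaussian jitter to pulse
times (in ms — the robustness sweeps cover 0–10 ms), and `pure_tone()`
represents a tone as a 200 Hz surrogate train, well above flutter, so the
kernels fuse into sustained net drive; its acceptance surface is the
temporal response profile, not exact rates.

## Response statistics and classification

For each repetition rate from 8 to 48 Hz (4-Hz grid):

* **Vector strength** $VS = \frac{1}{N}\left|\sum_n e^{2\pi i t_n/IPI}\right|$
  over spikes in the stimulus window shifted by the 10 ms synaptic delay;
  with zero spikes VS is undefined and signalled, never reported as 0.
* **Rayleigh statistic** $RS = 2\,N\,VS^2$, synchrony threshold 13.8.
* **Rate significance**: driven rate above the spontaneous mean + 2 sd and
  more than one spike per stimulus.
* **Sync** label: $VS > 0.1$ and $RS > 13.8$ at three or more consecutive
  grid rates, plus a significant rate response at some rate.
* **Monotonicity**: Spearman rank correlation of mean rate vs repetition
  rate; $\rho > 0.8$ ($p < 0.05$) positive, $\rho < -0.8$ negative,
  otherwise non-monotonic. With 11 rates the p-value comes from
  `cor.test(..., method = "spearman", exact = TRUE)` (the AS 89 exact/
  Edgeworth route; ties fall back to the t approximation) — full
  enumeration of the 11! permutations is unnecessary at this n.

`per_event_counts()` tiles the stimulus with windows
$[e_k + \ell,\, e_k + \ell + IPI)$ (latency $\ell$ = 10 ms for simulated
neurons), and `adaptation_strength()` reports $1 - r_{to}/r_{from}$ so 0
means no adaptation and positive values depression — the $1-\mathrm{ratio}$
transform is chosen because reference adaptation values are reported as
distances from 0. PSTHs are Gaussian-kernel smoothed (sd 10 ms) and
averaged across trials.

```{r classify, fig.width = 5, fig.height = 4}
fn <- simulate_neuron(plasticity = plasticity_params("depression",
                                                     A_DE = 0.4, A_DI = 0.1),
                      rates = seq(8, 48, by = 4), trials = 10, seed = 1)
fn
plot(fn)
```

## Experiments

`sweep_ei_plane()` classifies the plasticity-free model across excitation/
inhibition amplitudes (Sync− without plasticity needs I/E ratios far above
the plausible band, and those cells fail rate significance — the
motivation for STD). `sweep_adaptation_plane()` and `sweep_facilitation()`
map monotonicity over $(A_{DE}, A_{DI})$; `monotonicity_summary()` reports
the average positive/negative monotonicity index of a map, defined as the
mean Spearman coefficient over Sync+ (resp. Sync−) points with zeros
elsewhere — the index itself is simply the Spearman coefficient, the most
conservative reading of an otherwise undefined map statistic.
`robustness_suite()` re-runs the canonical configurations across noise,
jitter, excitation-strength and I/E axes. `canonical_pairing()` resolves
which of the swapped amplitude pairings `{0.4, 0.1}` / `{0.1, 0.4}` is
Sync+ by the measured sign of $\rho$ rather than by assumption, because
the mechanism (depression of excitation drives the negative slope) and
parts of the reference description disagree on the assignment.

Sweep grids default to 0.05 steps in $A_D$ and 0.01 s in $\tau_p$;
per-grid-point seeds are pre-assigned from the root seed, so maps are
reproducible and independent of execution order.

## What the generator does and does not emulate

The simulator *is* the data source: there is no external data set. It
emulates stimulus-locked spiking, spontaneous activity from membrane
noise, within-pool synaptic jitter, acoustic jitter, and per-pulse
resource dynamics. It does not emulate across-neuron heterogeneity of
biophysics, NMDA kinetics (synaptic time constants are fixed at 5 ms),
multiple inhibitory sources, network interactions, stimulus-specific
adaptation, or sinusoidally amplitude-modulated tones (whose bandwidth and
pulse width vary with modulation frequency and cannot be mapped to a fixed
kernel). Passing tests therefore validate the mechanism's sufficiency
in a single calibrated cell, not quantitative agreement with any real
recording; cross-neuron statistics from real data are out of scope.

Exact Spearman coefficients of example configurations are sensitive to
the threshold/reset/noise choices above, which the reference description
leaves unconstrained; the package pins only the constrained observables
(spontaneous ~4 spk/s, onset 40–60 spk/s) and reports the coefficients its
own calibration produces.

## Numerical and testing notes

* Sampled kernels are truncated at $12\tau_s$ (<2e-4 of peak).
* Kernel onsets are rounded to the integration grid (0.1 ms, well below
  the 1 ms synaptic jitter).
* All randomness flows through R's RNG; noise vectors are pre-drawn in R
  and passed to the compiled integrator, so trials are bit-for-bit
  reproducible from their seeds, and seeded calls restore the caller's RNG
  state.
* Divergent membrane values abort with the offending step index.
* The test and acceptance protocols use 10 trials per stimulus, 11 rates
  (8–48 Hz), and medians over 30 protocol seeds (100 seeds for the paired
  adaptation-ordering comparison; 60 s of silence for the spontaneous
  rate) — sizes at which the medians are stable to well under the
  comparison tolerances while keeping a full run in tens of seconds.

## Known limitations

* Single compartment, single cell; no top-down or lateral circuitry.
* AMPA/GABA-A only; one shared synaptic time constant.
* The pure-tone surrogate reproduces temporal response *profiles*
  (onset-dominated vs sustained), not absolute pure-tone rates, which are
  known to be exaggerated under sustained drive in this model class.
* Facilitation beyond $P_{rel} = 1$ is clipped; regimes that rely on
  unbounded facilitation are intentionally not representable.
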