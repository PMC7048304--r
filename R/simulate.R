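#' Simulate one trial of the model neuron
#'
#' Runs forward-Euler integration of the conductance-based leaky
#' integrate-and-fire membrane equation over a full trial (pre-stimulus
#' silence, stimulus, post-stimulus silence):
#'
#' `C dV/dt = g_e(E_e - V) + g_i(E_i - V) + g_rest(E_rest - V) + g_sra(E_K - V)`
#'
#' with per-step additive Gaussian voltage noise of sd
#' `sigma_noise * sqrt(dt)`. A spike is recorded whenever `V >= V_th`, after
#' which `V` is reset to `E_rest` (no explicit refractory period beyond the
#' reset). Short-term plasticity scales each event's conductance amplitude
#' by the per-event release probability (see [release_trace()]); the
#' spike-triggered adaptation conductance `g_sra` is incremented at each
#' output spike and decays with `tau_sra`.
#'
#' The RNG draw order within a trial is fixed (excitatory jitters,
#' inhibitory jitters, then the noise sequence), so a trial is bit-for-bit
#' reproducible from its seed.
#'
#' @param train a [pulse_train()] or [pure_tone()] stimulus.
#' @param neuron a [neuron_params()] object.
#' @param plasticity a [plasticity_params()] object.
#' @param seed optional integer seed for this trial; if `NULL` the current
#'   RNG stream is used.
#' @param keep_trace keep the membrane-potential and conductance traces
#'   (set `FALSE` in large sweeps to save memory).
#' @return An object of class `"trial_result"`: list with `spikes` (ms from
#'   trial start, ascending), `onset` (stimulus onset, ms), `times`, `V`,
#'   `g_e`, `g_i` (if `keep_trace`), `release_E`, `release_I` (per event),
#'   `train`, `seed`.
#' @examples
#' tr <- simulate_trial(pulse_train(8), neuron_params(), seed = 1)
#' length(tr$spikes)
#' @export
simulate_trial <- function(train, neuron = neuron_params(),
                           plasticity = plasticity_params(),
                           seed = NULL, keep_trace = TRUE) {
  stopifnot(inherits(train, "stimulus_train"), inherits(neuron, "neuron_params"),
            inherits(plasticity, "plasticity_params"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  rel_E <- release_trace(train$events, plasticity$A_DE, plasticity$tau_pE,
                         plasticity$P0_E)
  rel_I <- release_trace(train$events, plasticity$A_DI, plasticity$tau_pI,
                         plasticity$P0_I)
  g <- conductance_traces(train, neuron, rel_E, rel_I)
  noise <- rnorm(g$n_steps, 0, neuron$sigma_noise * sqrt(neuron$dt))
  res <- lif_integrate(g$g_e, g$g_i, noise,
                       C_pF = neuron$C * 1000, g_rest = neuron$g_rest,
                       E_e = neuron$E_e, E_i = neuron$E_i,
                       E_rest = neuron$E_rest, V_th = neuron$V_th,
                       dt = neuron$dt,
                       delta_g_sra = plasticity$delta_g_sra,
                       tau_sra = plasticity$tau_sra, E_K = plasticity$E_K,
                       keep_trace = keep_trace, V0 = neuron$E_rest)
  out <- list(spikes = res$spikes, onset = train$pre,
              release_E = rel_E, release_I = rel_I,
              train = train, seed = seed)
  if (keep_trace) {
    out$times <- g$times
    out$V <- res$V
    out$g_e <- g$g_e
    out$g_i <- g$g_i
  }
  structure(out, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial_result: %d spikes over %g ms (%s at %g Hz)\n",
              length(x$spikes), x$onset + x$train$duration + x$train$post,
              x$train$label, x$train$rate))
  invisible(x)
}

#' Simulate and classify a model neuron across repetition rates
#'
#' The central model-fitting-style entry point: runs `trials` independent
#' trials of the model neuron at each repetition rate, computes per-rate
#' response statistics (mean driven discharge rate, s.e.m., vector strength,
#' Rayleigh statistic, spikes per stimulus), estimates the spontaneous rate
#' from the pre-stimulus windows, and classifies the neuron by synchrony and
#' monotonicity (Spearman rank correlation of mean rate vs repetition rate
#' over 8-48 Hz) into Sync+/Sync-/SyncNM/nSync+/nSync-/nSyncNM or
#' non-responsive (see [classify_neuron()]).
#'
#' Per-trial seeds are pre-assigned from `seed` (one derived stream,
#' rate-major), so results are independent of execution order and
#' reproducible bit-for-bit.
#'
#' @param neuron a [neuron_params()] object.
#' @param plasticity a [plasticity_params()] object.
#' @param rates repetition rates (Hz) to test.
#' @param trials trials per rate.
#' @param duration,pre,post stimulus timing (ms).
#' @param jitter_sd temporal jitter applied to the acoustic pulse times
#'   (ms; 0 = none). Jitter is drawn independently per trial.
#' @param seed integer root seed.
#' @param keep_spikes keep the per-trial spike rasters in the returned
#'   object (needed for [psth()] / [per_event_counts()] follow-ups).
#' @return An object of class `"flutter_neuron"` with components `stats`
#'   (per-rate data frame), `spont` (mean/sd in spk/s), `rho`, `p`, `label`,
#'   `spikes` (nested list, `spikes[[rate]][[trial]]`, stimulus-relative ms),
#'   `rates`, `neuron`, `plasticity`, `seed`, `call`. Methods: `print`,
#'   `summary`, `plot`, `coef`, `simulate`.
#' @examples
#' \donttest{
#' fn <- simulate_neuron(plasticity = plasticity_params("depression",
#'         A_DE = 0.1, A_DI = 0.4), trials = 5, seed = 1)
#' fn
#' }
#' @export
simulate_neuron <- function(neuron = neuron_params(),
                            plasticity = plasticity_params(),
                            rates = seq(4, 48, by = 4), trials = 10,
                            duration = 500, pre = 500, post = 500,
                            jitter_sd = 0, seed = NULL,
                            keep_spikes = TRUE) {
  cl <- match.call()
  if (trials < 1) stop("trials must be >= 1")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  trial_seeds <- matrix(sample.int(.Machine$integer.max, length(rates) * trials),
                        nrow = length(rates))

  spikes <- vector("list", length(rates))
  names(spikes) <- as.character(rates)
  stats_rows <- vector("list", length(rates))
  spont_rates <- numeric(0)

  for (ri in seq_along(rates)) {
    r <- rates[ri]
    base <- pulse_train(r, duration = duration, pre = pre, post = post)
    per_trial <- vector("list", trials)
    driven <- numeric(trials)
    for (ti in seq_len(trials)) {
      set.seed(trial_seeds[ri, ti])
      tr_stim <- if (jitter_sd > 0) jitter_events(base, jitter_sd) else base
      tr <- simulate_trial(tr_stim, neuron, plasticity, keep_trace = FALSE)
      st <- tr$spikes - pre  # stimulus-relative
      per_trial[[ti]] <- st
      driven[ti] <- sum(st >= 0 & st < duration) / duration * 1000
      spont_rates <- c(spont_rates, sum(st < 0) / pre * 1000)
    }
    # synchrony window: stimulus period shifted by the synaptic delay
    win <- c(neuron$syn_delay, duration + neuron$syn_delay)
    pooled <- unlist(per_trial)
    vs <- tryCatch(vector_strength(pooled, ipi = 1000 / r, window = win),
                   flutterlif_insufficient_spikes = function(e) list(vs = NA_real_, n = 0L))
    stats_rows[[ri]] <- data.frame(
      rate = r,
      mean_rate = mean(driven),
      sem = sd(driven) / sqrt(trials),
      vs = vs$vs,
      rs = if (is.na(vs$vs)) NA_real_ else rayleigh_statistic(vs$vs, vs$n),
      n_spikes = vs$n,
      spikes_per_stim = mean(driven) * duration / 1000)
    spikes[[ri]] <- per_trial
  }
  stats <- do.call(rbind, stats_rows)
  spont <- list(mean = mean(spont_rates), sd = sd(spont_rates))

  # classification needs the full 8-48 Hz analysis grid (e.g. pure-tone
  # surrogates are run at a single high rate and stay unclassified)
  cls <- if (all(seq(8, 48, by = 4) %in% rates))
    classify_neuron(stats, spont_mean = spont$mean, spont_sd = spont$sd)
  else
    list(label = NA_character_, rho = NA_real_, p = NA_real_,
         sync = NA, responsive = NA)
  structure(list(stats = stats, spont = spont,
                 rho = cls$rho, p = cls$p, label = cls$label,
                 sync = cls$sync, responsive = cls$responsive,
                 spikes = if (keep_spikes) spikes else NULL,
                 rates = rates, trials = trials,
                 duration = duration, pre = pre, post = post,
                 jitter_sd = jitter_sd,
                 neuron = neuron, plasticity = plasticity,
                 seed = seed, call = cl),
            class = "flutter_neuron")
}

#' @export
print.flutter_neuron <- function(x, ...) {
  cat("Simulated model neuron (", x$plasticity$mode, " plasticity)\n", sep = "")
  cat(sprintf("  classification: %s\n", x$label))
  cat(sprintf("  monotonicity (Spearman, 8-48 Hz): rho = %.3f, p = %.3g\n",
              x$rho, x$p))
  cat(sprintf("  spontaneous rate: %.2f +/- %.2f spk/s\n",
              x$spont$mean, x$spont$sd))
  cat(sprintf("  %d trials x %d rates (%g-%g Hz)\n",
              x$trials, length(x$rates), min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
summary.flutter_neuron <- function(object, ...) {
  structure(list(stats = object$stats, spont = object$spont,
                 rho = object$rho, p = object$p, label = object$label,
                 onset = onset_rate(object)),
            class = "summary.flutter_neuron")
}

#' @export
print.summary.flutter_neuron <- function(x, ...) {
  cat("Per-rate response statistics:\n")
  print(x$stats, row.names = FALSE, digits = 3)
  cat(sprintf("\nSpontaneous: %.2f +/- %.2f spk/s; onset response: %.1f spk/s\n",
              x$spont$mean, x$spont$sd, x$onset))
  cat(sprintf("Spearman rho = %.3f (p = %.3g) -> %s\n", x$rho, x$p, x$label))
  invisible(x)
}

#' @export
coef.flutter_neuron <- function(object, ...) {
  with(object$plasticity,
       c(A_DE = A_DE, A_DI = A_DI, tau_pE = tau_pE, tau_pI = tau_pI,
         P0_E = P0_E, P0_I = P0_I, delta_g_sra = delta_g_sra,
         A_E = object$neuron$A_E, A_I = object$neuron$A_I))
}

#' Rate-tuning plot of a simulated neuron
#'
#' Mean driven discharge rate against repetition rate with s.e.m. error
#' bars; the dashed line marks the spontaneous rate.
#'
#' @param x a `"flutter_neuron"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.flutter_neuron <- function(x, ...) {
  s <- x$stats
  graphics::plot(s$rate, s$mean_rate, type = "b", pch = 16,
                 xlab = "Repetition rate (Hz)",
                 ylab = "Discharge rate (spk/s)",
                 ylim = range(0, s$mean_rate + s$sem),
                 main = sprintf("%s (rho = %.2f)", x$label, x$rho), ...)
  nz <- !is.na(s$sem) & s$sem > 0
  if (any(nz))
    graphics::arrows(s$rate[nz], s$mean_rate[nz] - s$sem[nz],
                     s$rate[nz], s$mean_rate[nz] + s$sem[nz],
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(h = x$spont$mean, lty = 2, col = "grey50")
  invisible(x)
}

#' Re-simulate spike rasters from a fitted model-neuron object
#'
#' Draws `nsim` fresh protocol repetitions (same neuron, plasticity, rates,
#' and trial count) under new seeds.
#'
#' @param object a `"flutter_neuron"` object.
#' @param nsim number of repetitions.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` `"flutter_neuron"` objects.
#' @export
simulate.flutter_neuron <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    simulate_neuron(object$neuron, object$plasticity, rates = object$rates,
                    trials = object$trials, duration = object$duration,
                    pre = object$pre, post = object$post,
                    jitter_sd = object$jitter_sd, seed = s,
                    keep_spikes = !is.null(object$spikes)))
}

#' Onset response rate of a simulated neuron
#'
#' Firing rate in the first post-onset analysis window (the first
#' inter-pulse interval, offset by the synaptic delay), averaged across
#' trials and repetition rates. The canonical calibrations place this in
#' the 40-60 spk/s band.
#'
#' @param x a `"flutter_neuron"` object (with spikes kept).
#' @param rates subset of repetition rates to average over (default: all
#'   rates in the object).
#' @return Onset rate (spk/s).
#' @export
onset_rate <- function(x, rates = x$rates) {
  stopifnot(inherits(x, "flutter_neuron"))
  if (is.null(x$spikes)) stop("object was built with keep_spikes = FALSE")
  lat <- x$neuron$syn_delay
  per_rate <- vapply(as.character(rates), function(rn) {
    r <- as.numeric(rn)
    ipi <- 1000 / r
    counts <- vapply(x$spikes[[rn]],
                     function(st) sum(st >= lat & st < lat + ipi), numeric(1))
    mean(counts) / ipi * 1000
  }, numeric(1))
  mean(per_rate)
}
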