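#' Canonical Sync+/Sync- parameter pairings, resolved empirically
#'
#' The canonical short-term-depression configurations swap the adaptation
#' amplitudes between the synapse classes: `{A_DE, A_DI} = {0.4, 0.1}` and
#' `{0.1, 0.4}` at `tau_pE = 0.15 s`, `tau_pI = 0.10 s`. Which pairing
#' yields the positive rate slope is resolved by simulation: both are run
#' and labelled by the measured sign of the Spearman coefficient, rather
#' than assumed. (Strong depression of excitation suppresses late pulses at
#' high rates, driving the negative slope; strong depression of inhibition
#' releases them, driving the positive slope.)
#'
#' @param neuron a [neuron_params()] object.
#' @param A_hi,A_lo the strong and weak adaptation amplitudes.
#' @param tau_pE,tau_pI recovery time constants (s).
#' @param trials,seed protocol settings for the resolving runs.
#' @return A list with `sync_plus` and `sync_minus` [plasticity_params()]
#'   objects, plus `rho` (named vector of the measured coefficients).
#' @export
canonical_pairing <- function(neuron = neuron_params(), A_hi = 0.4, A_lo = 0.1,
                              tau_pE = 0.15, tau_pI = 0.10,
                              trials = 10, seed = 1) {
  p1 <- plasticity_params("depression", A_DE = A_hi, A_DI = A_lo,
                          tau_pE = tau_pE, tau_pI = tau_pI)
  p2 <- plasticity_params("depression", A_DE = A_lo, A_DI = A_hi,
                          tau_pE = tau_pE, tau_pI = tau_pI)
  f1 <- simulate_neuron(neuron, p1, rates = seq(8, 48, 4), trials = trials,
                        seed = seed, keep_spikes = FALSE)
  f2 <- simulate_neuron(neuron, p2, rates = seq(8, 48, 4), trials = trials,
                        seed = seed, keep_spikes = FALSE)
  if (f1$rho >= f2$rho)
    list(sync_plus = p1, sync_minus = p2, rho = c(sync_plus = f1$rho, sync_minus = f2$rho))
  else
    list(sync_plus = p2, sync_minus = p1, rho = c(sync_plus = f2$rho, sync_minus = f1$rho))
}

#' Classification sweep over the excitation-inhibition plane
#'
#' With plasticity disabled, simulates and classifies one model neuron per
#' `(A_E, A_I)` grid point. The biologically plausible band is the set of
#' points with I/E ratio between 1.4 and 2.0 (marked in the `plausible`
#' column).
#'
#' @param E_values,I_values per-synapse peak amplitudes (nS) spanning the
#'   0-6 / 0-12 nS ranges.
#' @param neuron base [neuron_params()]; amplitudes are overridden per grid
#'   point.
#' @param rates,trials protocol settings.
#' @param seed root seed; per-point seeds are pre-assigned so results do
#'   not depend on execution order.
#' @return A data frame of class `"flutter_sweep"` with one row per grid
#'   point: `A_E`, `A_I`, `ie_ratio`, `plausible`, `rho`, `p`, `label`,
#'   `mean_rate_848` (grand mean driven rate over 8-48 Hz).
#' @export
sweep_ei_plane <- function(E_values = seq(0.5, 6, by = 0.5),
                           I_values = seq(0, 12, by = 1),
                           neuron = neuron_params(),
                           rates = seq(4, 48, by = 4), trials = 10,
                           seed = 1) {
  grid <- expand.grid(A_E = E_values, A_I = I_values)
  seeds <- preassigned_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    np <- neuron
    np$A_E <- grid$A_E[i]
    np$A_I <- grid$A_I[i]
    fn <- simulate_neuron(np, plasticity_params(), rates = rates,
                          trials = trials, seed = seeds[i],
                          keep_spikes = FALSE)
    s848 <- fn$stats[fn$stats$rate >= 8, ]
    data.frame(A_E = np$A_E, A_I = np$A_I,
               ie_ratio = if (np$A_E > 0) np$A_I / np$A_E else Inf,
               plausible = np$A_E > 0 && np$A_I / np$A_E >= 1.4 &&
                           np$A_I / np$A_E <= 2.0,
               rho = fn$rho, p = fn$p, label = fn$label,
               mean_rate_848 = mean(s848$mean_rate))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flutter_sweep", "data.frame")
  attr(out, "axes") <- c("A_E", "A_I")
  out
}

#' Monotonicity sweep over the adaptation-amplitude plane
#'
#' Simulates and classifies one model neuron per `(A_DE, A_DI)` grid point
#' at fixed recovery time constants. Works for depression grids (amplitudes
#' in `[0, 0.5]`), facilitation grids (`[-0.5, 0]`) and the mixed
#' depression-of-excitation / facilitation-of-inhibition regime, chosen by
#' `mode`.
#'
#' @param A_DE_values,A_DI_values adaptation-amplitude grids.
#' @param mode plasticity mode, see [plasticity_params()].
#' @param tau_pE,tau_pI recovery time constants (s).
#' @param neuron base [neuron_params()].
#' @param rates,trials,seed protocol settings (per-point seeds
#'   pre-assigned).
#' @return A `"flutter_sweep"` data frame with `A_DE`, `A_DI`, `rho`, `p`,
#'   `label`.
#' @seealso [monotonicity_summary()] for the average positive/negative
#'   monotonicity indices of a map.
#' @export
sweep_adaptation_plane <- function(A_DE_values = seq(0, 0.5, by = 0.05),
                                   A_DI_values = seq(0, 0.5, by = 0.05),
                                   mode = "depression",
                                   tau_pE = 0.15, tau_pI = 0.10,
                                   neuron = neuron_params(),
                                   rates = seq(4, 48, by = 4), trials = 10,
                                   seed = 1) {
  grid <- expand.grid(A_DE = A_DE_values, A_DI = A_DI_values)
  seeds <- preassigned_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pl <- plasticity_params(mode, A_DE = grid$A_DE[i], A_DI = grid$A_DI[i],
                            tau_pE = tau_pE, tau_pI = tau_pI)
    fn <- simulate_neuron(neuron, pl, rates = rates, trials = trials,
                          seed = seeds[i], keep_spikes = FALSE)
    data.frame(A_DE = grid$A_DE[i], A_DI = grid$A_DI[i],
               rho = fn$rho, p = fn$p, label = fn$label)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flutter_sweep", "data.frame")
  attr(out, "axes") <- c("A_DE", "A_DI")
  out
}

#' Monotonicity sweep for facilitation-bearing models
#'
#' Convenience wrapper around [sweep_adaptation_plane()] for the two
#' facilitation regimes: `"mixed"` (depression of excitation, facilitation
#' of inhibition; `A_DE` in `[0, 0.5]`, `A_DI` in `[-0.5, 0]`) and
#' `"facilitation"` (both classes facilitated, baselines `P_0 = 0.5`).
#'
#' @param mode `"mixed"` or `"facilitation"`.
#' @param A_DE_values,A_DI_values amplitude grids (signs must match the
#'   mode).
#' @inheritParams sweep_adaptation_plane
#' @return A `"flutter_sweep"` data frame.
#' @export
sweep_facilitation <- function(mode = c("mixed", "facilitation"),
                               A_DE_values = NULL, A_DI_values = NULL,
                               tau_pE = 0.15, tau_pI = 0.10,
                               neuron = neuron_params(),
                               rates = seq(4, 48, by = 4), trials = 10,
                               seed = 1) {
  mode <- match.arg(mode)
  if (is.null(A_DE_values))
    A_DE_values <- if (mode == "mixed") seq(0, 0.4, by = 0.1)
                   else seq(-0.4, 0, by = 0.1)
  if (is.null(A_DI_values)) A_DI_values <- seq(-0.4, 0, by = 0.1)
  sweep_adaptation_plane(A_DE_values, A_DI_values, mode = mode,
                         tau_pE = tau_pE, tau_pI = tau_pI, neuron = neuron,
                         rates = rates, trials = trials, seed = seed)
}

#' Average positive and negative monotonicity indices of a sweep map
#'
#' The monotonicity index of a grid point is its Spearman coefficient. The
#' average positive index is the mean of the coefficient over points
#' classified Sync+ (points with other labels contribute 0); the average
#' negative index likewise over Sync- points.
#'
#' @param sweep a `"flutter_sweep"` data frame.
#' @return A list with `avg_positive`, `avg_negative`, `n_sync_plus`,
#'   `n_sync_minus`.
#' @export
monotonicity_summary <- function(sweep) {
  stopifnot(inherits(sweep, "flutter_sweep"))
  pos <- ifelse(sweep$label == "Sync+", sweep$rho, 0)
  neg <- ifelse(sweep$label == "Sync-", sweep$rho, 0)
  list(avg_positive = mean(pos), avg_negative = mean(neg),
       n_sync_plus = sum(sweep$label == "Sync+"),
       n_sync_minus = sum(sweep$label == "Sync-"))
}

#' @export
print.flutter_sweep <- function(x, ...) {
  ax <- attr(x, "axes")
  cat(sprintf("Parameter sweep over (%s, %s): %d points\n", ax[1], ax[2], nrow(x)))
  print(table(x$label))
  invisible(x)
}

#' Heat-map plot of a sweep
#'
#' @param x a `"flutter_sweep"` data frame.
#' @param value column to map to colour (default `"rho"`).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.flutter_sweep <- function(x, value = "rho", ...) {
  ax <- attr(x, "axes")
  xs <- sort(unique(x[[ax[1]]]))
  ys <- sort(unique(x[[ax[2]]]))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(x[[ax[1]]], xs), match(x[[ax[2]]], ys))] <- x[[value]]
  graphics::image(xs, ys, z, xlab = ax[1], ylab = ax[2],
                  col = grDevices::hcl.colors(21, "RdBu", rev = TRUE),
                  zlim = c(-1, 1) * max(abs(z), na.rm = TRUE), ...)
  invisible(x)
}

#' Robustness of the canonical configurations
#'
#' Re-runs the canonical Sync+ and Sync- configurations while varying one
#' nuisance axis at a time — membrane noise scale, acoustic temporal
#' jitter, excitatory strength (I/E ratio held fixed), and I/E ratio
#' (excitatory strength held fixed) — and records the Spearman coefficient,
#' label, spontaneous rate and mean vector strength for each condition.
#'
#' @param sync_plus,sync_minus [plasticity_params()] for the two canonical
#'   configurations (e.g. from [canonical_pairing()]).
#' @param noise_amplitudes noise scales (mV/sqrt(ms)).
#' @param jitter_sigmas acoustic-pulse jitter sds (ms).
#' @param E_strengths per-synapse excitatory amplitudes (nS).
#' @param IE_ratios inhibitory/excitatory amplitude ratios.
#' @param neuron base [neuron_params()].
#' @param rates,trials,seed protocol settings.
#' @return A data frame with columns `config`, `axis`, `value`, `rho`, `p`,
#'   `label`, `spont_rate`, `mean_vs`, `mean_vs_48` (VS at 48 Hz).
#' @export
robustness_suite <- function(sync_plus, sync_minus,
                             noise_amplitudes = seq(1.5, 3.5, by = 0.5),
                             jitter_sigmas = c(0, 1, 2, 5, 10),
                             E_strengths = c(2, 3, 4.5, 6),
                             IE_ratios = c(0.5, 0.8, 1, 1.4, 1.9, 2.5),
                             neuron = neuron_params(),
                             rates = seq(8, 48, by = 4), trials = 10,
                             seed = 1) {
  configs <- list(sync_plus = sync_plus, sync_minus = sync_minus)
  conditions <- rbind(
    data.frame(axis = "noise", value = noise_amplitudes),
    data.frame(axis = "jitter", value = jitter_sigmas),
    data.frame(axis = "E_strength", value = E_strengths),
    data.frame(axis = "IE_ratio", value = IE_ratios))
  seeds <- preassigned_seeds(seed, 2 * nrow(conditions))
  k <- 0L
  rows <- list()
  for (cfg in names(configs)) {
    for (i in seq_len(nrow(conditions))) {
      k <- k + 1L
      np <- neuron
      jit <- 0
      ax <- conditions$axis[i]
      v <- conditions$value[i]
      if (ax == "noise") np$sigma_noise <- v
      if (ax == "jitter") jit <- v
      if (ax == "E_strength") {
        ratio <- np$A_I / np$A_E
        np$A_E <- v
        np$A_I <- v * ratio
      }
      if (ax == "IE_ratio") np$A_I <- np$A_E * v
      fn <- suppressWarnings(
        simulate_neuron(np, configs[[cfg]], rates = rates, trials = trials,
                        jitter_sd = jit, seed = seeds[k], keep_spikes = FALSE))
      rows[[k]] <- data.frame(config = cfg, axis = ax, value = v,
                              rho = fn$rho, p = fn$p, label = fn$label,
                              spont_rate = fn$spont$mean,
                              mean_vs = mean(fn$stats$vs, na.rm = TRUE),
                              vs_48 = fn$stats$vs[fn$stats$rate == 48])
    }
  }
  do.call(rbind, rows)
}

# pre-assigned per-point seeds derived once from the root seed
preassigned_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
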