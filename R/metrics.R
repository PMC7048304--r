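#' Vector strength of stimulus-locked spiking
#'
#' Mean resultant length of spike phases relative to the stimulus period:
#' `VS = (1/N) * sqrt((sum sin(2 pi t_n / IPI))^2 + (sum cos(2 pi t_n / IPI))^2)`
#' over the `N` spikes falling inside the analysis window. 1 means perfect
#' phase locking, 0 a uniform phase distribution.
#'
#' @param spike_times spike times (ms), on the same clock as `window`.
#' @param ipi inter-pulse interval (ms), `> 0`.
#' @param window length-2 analysis window `[lo, hi)` (ms); `NULL` uses all
#'   spikes.
#' @return A list with `vs` and `n` (spikes in window). With zero in-window
#'   spikes VS is undefined and a condition of class
#'   `"flutterlif_insufficient_spikes"` is signalled.
#' @examples
#' vector_strength(seq(0, 450, by = 50), ipi = 50)$vs  # 1
#' @export
vector_strength <- function(spike_times, ipi, window = NULL) {
  if (ipi <= 0) stop("ipi must be > 0")
  st <- spike_times
  if (!is.null(window)) st <- st[st >= window[1] & st < window[2]]
  n <- length(st)
  if (n == 0)
    stop(structure(class = c("flutterlif_insufficient_spikes", "error", "condition"),
                   list(message = "no spikes in window: vector strength undefined",
                        call = sys.call())))
  ph <- 2 * pi * st / ipi
  vs <- sqrt(sum(sin(ph))^2 + sum(cos(ph))^2) / n
  list(vs = vs, n = n)
}

#' Rayleigh statistic
#'
#' `RS = 2 * N * VS^2`, the significance statistic for a non-uniform phase
#' distribution; the classification threshold used throughout is
#' `RS > 13.8` (p < 0.001).
#'
#' @param vs vector strength in `[0, 1]`.
#' @param n number of spikes.
#' @return The Rayleigh statistic.
#' @export
rayleigh_statistic <- function(vs, n) {
  if (n < 1) stop("n must be >= 1")
  2 * n * vs^2
}

#' Significance of a driven rate response
#'
#' A rate response is significant when the average driven discharge rate
#' exceeds the mean spontaneous rate by more than 2 spontaneous standard
#' deviations and the stimulus evokes on average more than 1 spike.
#'
#' @param driven_rate mean driven rate (spk/s).
#' @param spont_mean,spont_sd spontaneous rate mean and sd (spk/s), from
#'   pre-stimulus windows.
#' @param spikes_per_stim mean spikes per stimulus presentation.
#' @return Logical.
#' @export
rate_response_significant <- function(driven_rate, spont_mean, spont_sd,
                                      spikes_per_stim) {
  if (is.na(spont_sd) || spont_sd < 0) spont_sd <- 0
  driven_rate > spont_mean + 2 * spont_sd & spikes_per_stim > 1
}

# Spearman correlation of mean rate vs repetition rate with the exact
# distribution where available (AS 89 via cor.test; t-approximation under
# ties). Two-sided.
spearman_monotonicity <- function(rates, mean_rates) {
  ct <- suppressWarnings(
    cor.test(rates, mean_rates, method = "spearman", exact = TRUE,
             alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Classify a neuron's synchrony and monotonicity
#'
#' Implements the two-stage decision rule on per-rate response statistics
#' over the 8-48 Hz analysis range:
#' \itemize{
#'   \item \strong{Responsive}: rate response significant (see
#'     [rate_response_significant()]) at one or more rates; otherwise
#'     `"non-responsive"`.
#'   \item \strong{Sync}: vector strength `> 0.1` with Rayleigh statistic
#'     `> 13.8` at three or more consecutive rates on the 4-Hz grid;
#'     otherwise nSync.
#'   \item \strong{Monotonicity}: Spearman rank correlation of mean rate vs
#'     repetition rate; `rho > 0.8` with `p < 0.05` is positive (+),
#'     `rho < -0.8` with `p < 0.05` negative (-), otherwise non-monotonic
#'     (NM).
#' }
#'
#' @param stats data frame with columns `rate`, `mean_rate`, `vs`, `rs`,
#'   `spikes_per_stim`, covering 8-48 Hz in 4-Hz steps (missing rates are an
#'   error).
#' @param spont_mean,spont_sd spontaneous rate statistics (spk/s).
#' @param analysis_rates rates over which synchrony and monotonicity are
#'   evaluated.
#' @return A list with `label` (one of `"Sync+"`, `"Sync-"`, `"SyncNM"`,
#'   `"nSync+"`, `"nSync-"`, `"nSyncNM"`, `"non-responsive"`), `rho`, `p`,
#'   `sync`, `responsive`.
#' @export
classify_neuron <- function(stats, spont_mean, spont_sd,
                            analysis_rates = seq(8, 48, by = 4)) {
  missing_rates <- setdiff(analysis_rates, stats$rate)
  if (length(missing_rates) > 0)
    stop("missing repetition rates: ", paste(missing_rates, collapse = ", "))
  s <- stats[match(analysis_rates, stats$rate), ]

  sig <- rate_response_significant(s$mean_rate, spont_mean, spont_sd,
                                   s$spikes_per_stim)
  responsive <- any(sig)

  locked <- !is.na(s$vs) & s$vs > 0.1 & !is.na(s$rs) & s$rs > 13.8
  sync <- has_run(locked, 3L) && responsive

  mono <- spearman_monotonicity(s$rate, s$mean_rate)
  dir <- if (!is.na(mono$rho) && !is.na(mono$p) && mono$p < 0.05) {
    if (mono$rho > 0.8) "+" else if (mono$rho < -0.8) "-" else "NM"
  } else "NM"

  label <- if (!responsive) "non-responsive"
           else paste0(if (sync) "Sync" else "nSync", dir)
  list(label = label, rho = mono$rho, p = mono$p,
       sync = sync, responsive = responsive)
}

# TRUE if x (logical) contains a run of at least k consecutive TRUEs
has_run <- function(x, k) {
  r <- rle(x)
  any(r$values & r$lengths >= k)
}

#' Spike counts per acoustic event
#'
#' Counts spikes in the non-overlapping windows
#' `[event + latency, event + latency + IPI)` tiling the stimulus, one per
#' acoustic event. Windows extending past `trace_end` are truncated and
#' flagged in the `"truncated"` attribute.
#'
#' @param spike_times spike times (ms, stimulus-relative).
#' @param train a [pulse_train()] object.
#' @param latency response latency (ms); defaults to the 10 ms synaptic
#'   delay of the simulated neuron.
#' @param trace_end end of the recorded trace (ms, stimulus-relative);
#'   default `duration + post`.
#' @return Integer vector of per-event counts.
#' @export
per_event_counts <- function(spike_times, train, latency = 10,
                             trace_end = train$duration + train$post) {
  stopifnot(inherits(train, "stimulus_train"))
  if (latency < 0) stop("latency must be >= 0")
  ipi <- 1000 / train$rate
  lo <- train$events + latency
  hi <- pmin(lo + ipi, trace_end)
  counts <- vapply(seq_along(lo),
                   function(k) sum(spike_times >= lo[k] & spike_times < hi[k]),
                   integer(1))
  attr(counts, "truncated") <- any(lo + ipi > trace_end)
  counts
}

#' Strength of adaptation between two acoustic events
#'
#' Firing rate in the window of event `to` relative to the window of event
#' `from`, reported as `1 - rate_to/rate_from`, so 0 means no adaptation,
#' positive values depression, negative facilitation. Counts are averaged
#' across trials before forming the ratio; since the two windows have equal
#' width the count ratio equals the rate ratio.
#'
#' @param counts_by_trial matrix (trials x events) of per-event spike counts
#'   ([per_event_counts()] per row), or a vector of trial-averaged counts.
#' @param from,to event indices (1-based).
#' @return Adaptation strength (dimensionless). Zero mean count at the
#'   reference event makes the ratio undefined: `NA` is returned with a
#'   warning.
#' @export
adaptation_strength <- function(counts_by_trial, from = 1, to = 2) {
  m <- if (is.matrix(counts_by_trial)) colMeans(counts_by_trial)
       else as.numeric(counts_by_trial)
  if (from < 1 || to < 1 || from > length(m) || to > length(m))
    stop("event index out of range")
  if (m[from] <= 0) {
    warning("zero firing rate at reference event: adaptation undefined")
    return(NA_real_)
  }
  1 - m[to] / m[from]
}

#' Gaussian-kernel peri-stimulus time histogram
#'
#' Smooths each trial's spike train with a Gaussian kernel (default sd
#' 10 ms) and averages across trials; units are spk/s, so the time-integral
#' of a single-trial PSTH equals its spike count (up to edge truncation).
#'
#' @param spike_trains list of per-trial spike-time vectors (ms).
#' @param sigma kernel sd (ms), `> 0`.
#' @param t_range length-2 time range of the grid (ms).
#' @param dt_grid grid step (ms).
#' @return An object of class `"psth"`: list with `time` (ms), `rate`
#'   (spk/s), `sigma`, `n_trials`.
#' @export
psth <- function(spike_trains, sigma = 10, t_range, dt_grid = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (!is.list(spike_trains)) spike_trains <- list(spike_trains)
  grid <- seq(t_range[1], t_range[2], by = dt_grid)
  acc <- numeric(length(grid))
  for (st in spike_trains) {
    for (s in st) acc <- acc + dnorm(grid, mean = s, sd = sigma)
  }
  rate <- 1000 * acc / length(spike_trains)  # spikes/ms -> spk/s
  structure(list(time = grid, rate = rate, sigma = sigma,
                 n_trials = length(spike_trains)), class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d trials, sigma = %g ms, peak %.1f spk/s\n",
              x$n_trials, x$sigma, max(x$rate)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  graphics::plot(x$time, x$rate, type = "l", xlab = "Time (ms)",
                 ylab = "Rate (spk/s)", ...)
  invisible(x)
}

#' Median spike time within the stimulus window
#'
#' Median of all spike times falling in `window`, reported relative to the
#' window start. Used to separate sustained (late median) from onset-only
#' (early median) pure-tone response profiles.
#'
#' @param spike_times spike times (ms).
#' @param window length-2 interval `[lo, hi)` (ms), typically the stimulus
#'   presentation period.
#' @return Median spike time (ms from window start); errors when the window
#'   contains no spikes.
#' @export
median_spike_time <- function(spike_times, window) {
  st <- spike_times[spike_times >= window[1] & spike_times < window[2]]
  if (length(st) == 0)
    stop(structure(class = c("flutterlif_insufficient_spikes", "error", "condition"),
                   list(message = "no spikes in window: median undefined",
                        call = sys.call())))
  median(st) - window[1]
}
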