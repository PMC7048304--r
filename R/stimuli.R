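#' Acoustic pulse-train stimulus
#'
#' Generates the event schedule of a periodic acoustic pulse train. Events
#' are placed at `k/rate` seconds for `k = 0, 1, ...` on the half-open
#' interval `[0, duration)`, so the first pulse falls at stimulus onset and
#' the event count is `ceiling(rate * duration / 1000)`. Times are in ms
#' relative to stimulus onset; the trial additionally carries pre- and
#' post-stimulus silent periods.
#'
#' @param rate repetition rate (Hz); the flutter range studied here is
#'   4-48 Hz in 4-Hz steps.
#' @param duration stimulus duration (ms).
#' @param pre,post pre- and post-stimulus silence (ms).
#' @param label stimulus class label, `"pulse_train"` or `"pure_tone"`.
#' @return An object of class `"stimulus_train"`: a list with fields `rate`,
#'   `duration`, `pre`, `post`, `events` (ms, ascending, stimulus-relative),
#'   `jitter_sd` (ms, 0 until [jitter_events()] is applied) and `label`.
#' @examples
#' pulse_train(8)$events   # 0, 125, 250, 375
#' length(pulse_train(48)$events)  # 24
#' @export
pulse_train <- function(rate, duration = 500, pre = 500, post = 500,
                        label = "pulse_train") {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  if (duration <= 0) stop("duration must be > 0")
  if (pre < 0 || post < 0) stop("pre/post silence must be >= 0")
  ipi <- 1000 / rate
  # half-open [0, duration): k/rate for k = 0 .. ceil(rate*duration/1000)-1,
  # built from integer k to avoid accumulation/fuzz placing an event at offset
  n_ev <- ceiling(rate * duration / 1000 - 1e-9)
  events <- (seq_len(n_ev) - 1) * ipi
  structure(list(rate = rate, duration = duration, pre = pre, post = post,
                 events = events, jitter_sd = 0, label = label),
            class = "stimulus_train")
}

#' Pure-tone surrogate stimulus
#'
#' A pure tone is represented as a pulse train at a repetition rate far above
#' the flutter range, so that successive conductance kernels fuse into a
#' sustained net drive: onset excitation followed by lagging inhibition. The
#' surrogate passes through the same synaptic and plasticity machinery as
#' ordinary pulse trains.
#'
#' @param duration tone duration (ms).
#' @param effective_rate surrogate event rate (Hz); should sit above the
#'   flutter range (default 200 Hz).
#' @inheritParams pulse_train
#' @return A `"stimulus_train"` labelled `"pure_tone"`.
#' @examples
#' length(pure_tone(200)$events)  # 40
#' @export
pure_tone <- function(duration = 200, effective_rate = 200,
                      pre = 500, post = 500) {
  if (effective_rate <= 48)
    warning("effective_rate <= 48 Hz is within the flutter range")
  pulse_train(effective_rate, duration = duration, pre = pre, post = post,
              label = "pure_tone")
}

#' Temporal jitter of acoustic pulse times
#'
#' Perturbs each event time by independent Gaussian noise of sd `sigma` ms,
#' re-sorts, and clamps events that fall before stimulus onset to 0. Jitter
#' is the only stochastic element of stimulus generation; it draws from R's
#' RNG, so results are reproducible under `set.seed()` (or via `seed`).
#'
#' @param train a [pulse_train()] object.
#' @param sigma jitter standard deviation (ms).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (and advanced).
#' @return The jittered `"stimulus_train"` with `jitter_sd` recorded.
#' @export
jitter_events <- function(train, sigma, seed = NULL) {
  stopifnot(inherits(train, "stimulus_train"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(train)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  ev <- train$events + rnorm(length(train$events), 0, sigma)
  ev <- sort(pmax(ev, 0))
  train$events <- ev
  train$jitter_sd <- sigma
  train
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("%s: %g Hz, %g ms, %d events (pre %g / post %g ms silence)",
              x$label, x$rate, x$duration, length(x$events), x$pre, x$post))
  if (x$jitter_sd > 0) cat(sprintf(", jitter sd %g ms", x$jitter_sd))
  cat("\n")
  invisible(x)
}

# save/restore helpers so seeded calls do not perturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
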