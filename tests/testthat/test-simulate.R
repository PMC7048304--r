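silent_train <- function(dur = 1000, pre = 0, post = 0) {
  tr <- pulse_train(1, duration = dur, pre = pre, post = post)
  tr$events <- numeric(0)
  tr
}

test_that("without drive or noise the membrane sits at rest and never spikes", {
  np <- neuron_params(sigma_noise = 0)
  tr <- simulate_trial(silent_train(), np, seed = 1)
  expect_length(tr$spikes, 0)
  expect_true(all(abs(tr$V - np$E_rest) < 1e-12))
})

test_that("leak-only dynamics decay exponentially with tau_m = C/g_rest = 10 ms", {
  np <- neuron_params(sigma_noise = 0, dt = 0.005)
  n <- round(30 / np$dt)
  res <- flutterlif:::lif_integrate(numeric(n), numeric(n), numeric(n),
                                    C_pF = np$C * 1000, g_rest = np$g_rest,
                                    E_e = np$E_e, E_i = np$E_i,
                                    E_rest = np$E_rest, V_th = np$V_th,
                                    dt = np$dt, delta_g_sra = 0, tau_sra = 50,
                                    E_K = -85, keep_trace = TRUE, V0 = -55)
  times <- seq_len(n) * np$dt
  tau_m <- 1000 * np$C / np$g_rest
  expect_equal(tau_m, 10)
  expected <- np$E_rest + (-55 - np$E_rest) * exp(-times / tau_m)
  # forward Euler at dt = 0.005 ms tracks the closed form to < 0.1 % of the
  # initial 10 mV displacement
  expect_lt(max(abs(res$V - expected)) / 10, 1e-3)
})

test_that("spike trains are reproducible bit-for-bit from the seed", {
  tr1 <- simulate_trial(pulse_train(24), seed = 11, keep_trace = FALSE)
  tr2 <- simulate_trial(pulse_train(24), seed = 11, keep_trace = FALSE)
  expect_identical(tr1$spikes, tr2$spikes)
  tr3 <- simulate_trial(pulse_train(24), seed = 12, keep_trace = FALSE)
  expect_false(identical(tr1$spikes, tr3$spikes))

  fn1 <- simulate_neuron(trials = 3, rates = c(8, 24, 48), seed = 5)
  fn2 <- simulate_neuron(trials = 3, rates = c(8, 24, 48), seed = 5)
  expect_identical(fn1$spikes, fn2$spikes)
  expect_identical(fn1$stats, fn2$stats)
})

test_that("spike times are strictly increasing and inside the trial", {
  tr <- simulate_trial(pulse_train(48), seed = 3, keep_trace = FALSE)
  expect_true(all(diff(tr$spikes) > 0))
  expect_true(all(tr$spikes > 0 & tr$spikes <= 1500))
})

test_that("spontaneous rate increases with the noise scale", {
  r <- vapply(c(2.2, 2.8, 3.4), function(s)
    spontaneous_rate(neuron_params(sigma_noise = s), duration_s = 10,
                     seeds = 1:3), numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("disabled mechanisms reproduce the base model exactly", {
  # SFA with delta_g = 0 and depression with A_D = 0 leave the spike train
  # bit-identical under the same seed
  base <- simulate_trial(pulse_train(24), seed = 9, keep_trace = FALSE)
  sfa0 <- simulate_trial(pulse_train(24),
                         plasticity = plasticity_params(delta_g_sra = 0),
                         seed = 9, keep_trace = FALSE)
  dep0 <- simulate_trial(pulse_train(24),
                         plasticity = plasticity_params("depression",
                                                        A_DE = 0, A_DI = 0),
                         seed = 9, keep_trace = FALSE)
  expect_identical(base$spikes, sfa0$spikes)
  expect_identical(base$spikes, dep0$spikes)
})

test_that("spike-frequency adaptation suppresses sustained firing", {
  strong <- plasticity_params(delta_g_sra = 50, tau_sra = 50)
  n_base <- length(simulate_trial(pulse_train(48), seed = 4,
                                  keep_trace = FALSE)$spikes)
  n_sfa <- length(simulate_trial(pulse_train(48), plasticity = strong,
                                 seed = 4, keep_trace = FALSE)$spikes)
  expect_lt(n_sfa, n_base)
})

test_that("per-event evoked counts are rate-invariant without plasticity (Sync+ regime)", {
  np <- neuron_params(A_I = 5)
  per_event <- function(rate, trials = 50) {
    tr <- pulse_train(rate)
    mean(vapply(seq_len(trials), function(s) {
      set.seed(s)
      r <- simulate_trial(tr, np, keep_trace = FALSE)
      st <- r$spikes - r$onset
      mean(vapply(tr$events, function(e)
        sum(st >= e + 10 & st < e + 30), numeric(1)))
    }, numeric(1)))
  }
  c8 <- per_event(8)
  c48 <- per_event(48)
  expect_lt(abs(c8 - c48) / c8, 0.15)
})

test_that("simulate_neuron classifies the canonical depression configurations", {
  plus <- simulate_neuron(plasticity = canonical_sync_plus(),
                          rates = seq(8, 48, 4), seed = 1)
  minus <- simulate_neuron(plasticity = canonical_sync_minus(),
                           rates = seq(8, 48, 4), seed = 1)
  expect_identical(plus$label, "Sync+")
  expect_identical(minus$label, "Sync-")
  expect_gt(plus$rho, 0.8)
  expect_lt(minus$rho, -0.8)
  # onset response is set by E/I strength, not by the depression parameters
  expect_equal(onset_rate(plus), onset_rate(minus), tolerance = 0.15)
})

test_that("flutter_neuron methods expose the protocol results", {
  fn <- simulate_neuron(plasticity = canonical_sync_plus(), trials = 3,
                        seed = 2)
  expect_s3_class(fn, "flutter_neuron")
  expect_named(fn$stats, c("rate", "mean_rate", "sem", "vs", "rs",
                           "n_spikes", "spikes_per_stim"))
  expect_output(print(fn), "Sync")
  expect_output(print(summary(fn)), "Spearman")
  expect_true(all(c("A_DE", "A_DI", "A_E") %in% names(coef(fn))))
  sims <- simulate(fn, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "flutter_neuron")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fn))
})

test_that("seeded simulation leaves the caller's RNG stream untouched", {
  set.seed(42)
  x1 <- rnorm(1)
  set.seed(42)
  invisible(simulate_trial(pulse_train(8), seed = 99, keep_trace = FALSE))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})
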