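test_that("vector strength is 1 for locked, 0 for antiphase, small for uniform", {
  locked <- vector_strength(seq(0, 9) * 50, ipi = 50)
  expect_equal(locked$vs, 1)
  expect_equal(locked$n, 10L)

  anti <- vector_strength(c(seq(0, 4) * 50, seq(0, 4) * 50 + 25), ipi = 50)
  expect_equal(anti$vs, 0, tolerance = 1e-12)

  set.seed(1)
  unif <- vector_strength(runif(1e4, 0, 1e5), ipi = 50)
  expect_lt(unif$vs, 0.05)

  expect_error(vector_strength(numeric(0), ipi = 50),
               class = "flutterlif_insufficient_spikes")
  expect_error(vector_strength(c(200, 300), ipi = 50, window = c(0, 100)),
               class = "flutterlif_insufficient_spikes")
})

test_that("vector strength matches an independent circular-statistics oracle", {
  set.seed(2)
  for (i in 1:20) {
    st <- sort(runif(sample(5:200, 1), 0, 500))
    ipi <- runif(1, 10, 125)
    vs <- vector_strength(st, ipi)$vs
    # oracle: mean resultant length of the phase distribution via complex
    # exponentials
    oracle <- Mod(mean(exp(2i * pi * st / ipi)))
    expect_equal(vs, oracle, tolerance = 1e-12)
  }
})

test_that("Rayleigh statistic is 2 N VS^2", {
  expect_equal(rayleigh_statistic(1, 10), 20)
  expect_equal(rayleigh_statistic(0, 500), 0)
  # threshold boundary: VS = 0.1 with N = 690 sits exactly at 13.8
  expect_equal(rayleigh_statistic(0.1, 690), 13.8)
  expect_error(rayleigh_statistic(0.5, 0), "n")
})

test_that("rate-response significance needs 2 sd above spontaneous and >1 spike", {
  expect_true(rate_response_significant(40, 4, 1, 20))
  expect_false(rate_response_significant(5, 4, 1, 3))
  expect_false(rate_response_significant(50, 4, 1, 0.8))
  # zero-variance spontaneous estimate degrades to a mean-only threshold
  expect_true(rate_response_significant(5, 4, 0, 2))
})

fake_stats <- function(mean_rates, vs = 0.6, n = 200) {
  data.frame(rate = seq(8, 48, by = 4), mean_rate = mean_rates, vs = vs,
             rs = rayleigh_statistic(vs, n), spikes_per_stim = mean_rates / 2)
}

test_that("classification follows the synchrony and monotonicity rules", {
  up <- fake_stats(seq(20, 70, by = 5))
  cls <- classify_neuron(up, spont_mean = 4, spont_sd = 1)
  expect_identical(cls$label, "Sync+")
  expect_equal(cls$rho, 1)

  down <- classify_neuron(fake_stats(seq(70, 20, by = -5)), 4, 1)
  expect_identical(down$label, "Sync-")
  expect_equal(down$rho, -1)

  # |rho| below 0.8 -> non-monotonic even when synchrony holds
  humped <- classify_neuron(fake_stats(c(20, 30, 40, 45, 50, 48, 44, 40, 35,
                                         30, 25)), 4, 1)
  expect_identical(humped$label, "SyncNM")
  expect_lt(abs(humped$rho), 0.8)

  # synchrony fails without 3 consecutive locked rates
  vs_pattern <- c(0.5, 0.05, 0.5, 0.05, 0.5, 0.05, 0.5, 0.05, 0.5, 0.05, 0.5)
  nsync <- classify_neuron(fake_stats(seq(20, 70, by = 5), vs = vs_pattern), 4, 1)
  expect_identical(nsync$label, "nSync+")

  # driven rates below spontaneous + 2 sd -> non-responsive
  weak <- fake_stats(rep(4.5, 11))
  weak$spikes_per_stim <- rep(0.5, 11)
  expect_identical(classify_neuron(weak, 4, 1)$label, "non-responsive")

  expect_error(classify_neuron(fake_stats(seq(20, 70, 5))[-3, ], 4, 1),
               "missing repetition rates")
})

test_that("Spearman rho is +/-1 for any strictly monotone profile", {
  for (profile in list(exp(seq(0, 2, length.out = 11)),
                       c(1, 2, 4, 8, 9, 9.5, 20, 21, 22, 30, 31),
                       -seq(1, 11)^2)) {
    cls <- classify_neuron(fake_stats(profile), 0, 0.1)
    expect_equal(abs(cls$rho), 1)
    expect_lt(cls$p, 0.05)
  }
})

test_that("classification is invariant to trial order and time translation", {
  st <- sort(runif(300, 0, 500))
  ipi <- 1000 / 24
  v0 <- vector_strength(st, ipi, window = c(10, 510))$vs
  v_shift <- vector_strength(st + 1000, ipi, window = c(1010, 1510))$vs
  expect_equal(v0, v_shift, tolerance = 1e-9)
  v_perm <- vector_strength(sample(st), ipi, window = c(10, 510))$vs
  expect_equal(v0, v_perm)
})

test_that("per-event counts tile the stimulus with latency-shifted windows", {
  tr <- pulse_train(8)
  st <- tr$events + 12  # one spike 12 ms after each event
  expect_equal(as.numeric(per_event_counts(st, tr, latency = 10)),
               rep(1, 4))
  expect_equal(as.numeric(per_event_counts(numeric(0), tr)), rep(0, 4))
  # truncation flag when the last window runs past the trace end
  short <- per_event_counts(st, tr, latency = 10, trace_end = 450)
  expect_true(attr(short, "truncated"))
})

test_that("adaptation strength is 1 - rate ratio", {
  expect_equal(adaptation_strength(matrix(c(2, 2, 2, 2), 2), 1, 2), 0)
  expect_equal(adaptation_strength(c(4, 2, 1), 1, 2), 0.5)
  expect_equal(adaptation_strength(c(4, 2, 1), 1, 3), 0.75)
  expect_equal(adaptation_strength(c(2, 3), 1, 2), -0.5)  # facilitation
  expect_warning(res <- adaptation_strength(c(0, 2), 1, 2), "undefined")
  expect_true(is.na(res))
  expect_error(adaptation_strength(c(1, 2), 1, 5), "out of range")
})

test_that("PSTH conserves spike mass and recovers a constant rate", {
  p1 <- psth(list(100), sigma = 10, t_range = c(0, 200), dt_grid = 0.5)
  # integral (spk/s * s) equals the spike count for interior spikes
  expect_equal(sum(p1$rate) * 0.5 / 1000, 1, tolerance = 0.01)
  expect_equal(p1$time[which.max(p1$rate)], 100)

  p0 <- psth(list(numeric(0), numeric(0)), sigma = 10, t_range = c(0, 100))
  expect_true(all(p0$rate == 0))

  set.seed(3)
  lambda <- 50  # spk/s
  trains <- replicate(40, sort(runif(rpois(1, lambda), 0, 1000)), simplify = FALSE)
  pp <- psth(trains, sigma = 10, t_range = c(100, 900))
  expect_equal(mean(pp$rate), lambda, tolerance = 0.1)
})

test_that("median spike time summarizes onset vs sustained responses", {
  expect_equal(median_spike_time(c(10, 20, 30), c(0, 200)), 20)
  expect_equal(median_spike_time(c(510, 520, 530), c(500, 700)), 20)
  expect_lt(median_spike_time(c(5, 12, 18, 25, 40), c(0, 200)), 50)
  expect_error(median_spike_time(c(300), c(0, 200)),
               class = "flutterlif_insufficient_spikes")
})
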