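test_that("canonical pairing resolves one Sync+ and one Sync- configuration", {
  pairing <- canonical_pairing(trials = 10, seed = 1)
  expect_gt(pairing$rho["sync_plus"], 0.8)
  expect_lt(pairing$rho["sync_minus"], -0.8)
  # the positive slope comes from weak depression of excitation
  expect_lt(pairing$sync_plus$A_DE, pairing$sync_plus$A_DI)
  expect_gt(pairing$sync_minus$A_DE, pairing$sync_minus$A_DI)
})

test_that("E/I plane sweep reproduces the reference regimes", {
  # strong inhibition, weak excitation: decreasing trend but no Sync- label
  # (rate responses too weak); balanced strengths in the plausible band: Sync+
  sw <- sweep_ei_plane(E_values = c(2, 4.5), I_values = c(8.5, 10),
                       rates = seq(8, 48, by = 4), trials = 10, seed = 2)
  weak <- sw[sw$A_E == 2 & sw$A_I == 10, ]
  expect_lt(weak$rho, 0)
  expect_false(weak$label == "Sync-")
  strong <- sw[sw$A_E == 4.5 & sw$A_I == 8.5, ]
  expect_identical(strong$label, "Sync+")
  expect_true(strong$plausible)
  # no lagging inhibition at all: monotone net excitation with rate
  solo <- sweep_ei_plane(E_values = 3.5, I_values = 0,
                         rates = seq(8, 48, by = 4), trials = 10, seed = 2)
  expect_identical(solo$label, "Sync+")
})

test_that("adaptation plane at A_D = 0 reduces to the plasticity-free model", {
  sw <- sweep_adaptation_plane(A_DE_values = 0, A_DI_values = 0,
                               rates = seq(8, 48, 4), trials = 5, seed = 7)
  ref_seed <- flutterlif:::preassigned_seeds(7, 1)
  ref <- simulate_neuron(plasticity = plasticity_params(),
                         rates = seq(8, 48, 4), trials = 5, seed = ref_seed,
                         keep_spikes = FALSE)
  expect_equal(sw$rho, ref$rho)
  expect_identical(sw$label, ref$label)
})

test_that("adaptation plane separates Sync+ and Sync- corners", {
  sw <- sweep_adaptation_plane(A_DE_values = c(0.1, 0.4),
                               A_DI_values = c(0.1, 0.4),
                               rates = seq(8, 48, 4), trials = 10, seed = 3)
  expect_identical(sw$label[sw$A_DE == 0.1 & sw$A_DI == 0.4], "Sync+")
  expect_identical(sw$label[sw$A_DE == 0.4 & sw$A_DI == 0.1], "Sync-")
  ms <- monotonicity_summary(sw)
  expect_gte(ms$n_sync_plus, 1)
  expect_gte(ms$n_sync_minus, 1)
  expect_gt(ms$avg_positive, 0)
  expect_lt(ms$avg_negative, 0)
})

test_that("facilitation sweeps validate amplitude signs via the mode", {
  expect_error(sweep_facilitation("facilitation", A_DE_values = 0.2,
                                  A_DI_values = -0.2, trials = 2, seed = 1),
               "facilitation")
  expect_error(plasticity_params("mixed", A_DE = 0.7, A_DI = -0.4),
               "\\[-0.5, 0.5\\]")
})

test_that("run_experiment writes a reproducible bundle and validates configs", {
  cfg <- flutter_preset("sync_plus")
  cfg$stimulus$rates <- seq(8, 48, by = 4)
  cfg$experiment$trials <- 3

  out1 <- file.path(tempdir(), "exp1")
  out2 <- file.path(tempdir(), "exp2")
  r1 <- run_experiment(cfg, out1, seed = 5)
  r2 <- run_experiment(cfg, out2, seed = 5)
  expect_true(all(file.exists(r1$paths)))
  expect_identical(readLines(file.path(out1, "raster.csv")),
                   readLines(file.path(out2, "raster.csv")))
  expect_identical(readLines(file.path(out1, "stats.csv")),
                   readLines(file.path(out2, "stats.csv")))
  cls <- jsonlite::read_json(file.path(out1, "classification.json"))
  expect_true(cls$label %in% c("Sync+", "Sync-", "SyncNM", "nSync+", "nSync-",
                               "nSyncNM", "non-responsive", NA))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$seed, 5)

  bad <- cfg
  bad$neuron$bogus_key <- 1
  expect_error(run_experiment(bad, tempdir(), seed = 1), "bogus_key")
  bad2 <- cfg
  bad2$typo_section <- list()
  expect_error(run_experiment(bad2, tempdir(), seed = 1), "typo_section")

  unlink(c(out1, out2), recursive = TRUE)
})

test_that("run_experiment round-trips a YAML config", {
  cfg <- flutter_preset("sync_minus")
  cfg$stimulus$rates <- c(8, 48)
  cfg$experiment$trials <- 2
  yml <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  out <- file.path(tempdir(), "exp_yaml")
  res <- run_experiment(yml, out, seed = 4)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_s3_class(res$result, "flutter_neuron")
  unlink(out, recursive = TRUE)
  unlink(yml)
})

test_that("robustness axes vary one parameter at a time", {
  tab <- robustness_suite(canonical_sync_plus(), canonical_sync_minus(),
                          noise_amplitudes = c(2.4, 3.2),
                          jitter_sigmas = c(0, 5),
                          E_strengths = 3.5,
                          IE_ratios = c(0.8, 1.9),
                          rates = seq(8, 48, by = 4), trials = 5, seed = 6)
  expect_equal(nrow(tab), 2 * 7)
  expect_true(all(c("config", "axis", "value", "rho", "label") %in% names(tab)))
  # spontaneous rate rises with the noise scale
  sp <- tab[tab$axis == "noise" & tab$config == "sync_plus", ]
  expect_lt(sp$spont_rate[sp$value == 2.4], sp$spont_rate[sp$value == 3.2])
})
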