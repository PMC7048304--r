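Package: flutterlif
Title: Conductance-Based Integrate-and-Fire Models of Monotonic Rate Coding
    for Acoustic Flutter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates conductance-based leaky integrate-and-fire auditory
    cortical neurons driven by acoustic pulse trains in the flutter range
    (4-48 Hz), with short-term synaptic depression and facilitation
    (release-probability dynamics) and spike-frequency adaptation. Provides
    stimulus generators, spike-train response statistics (vector strength,
    Rayleigh statistic, Gaussian-kernel PSTH, per-event spike counts,
    adaptation strength), Spearman-based monotonicity classification into
    synchronized positive/negative rate-coding classes (Sync+/Sync-), and
    parameter-sweep experiments over excitation-inhibition balance and
    plasticity parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
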