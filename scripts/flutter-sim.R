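#!/usr/bin/env Rscript

# Thin command-line front end over the flutterlif package.
#
#   Rscript scripts/flutter-sim.R --preset sync_plus --seed 1 --out out/
#   Rscript scripts/flutter-sim.R --config my_experiment.yaml --seed 1 --out out/
#
# A config file (YAML, sections [neuron], [plasticity], [stimulus],
# [experiment]) overrides any preset; see ?flutter_preset and
# ?run_experiment for the schema and available experiment types.

suppressPackageStartupMessages({
  library(optparse)
  library(flutterlif)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML experiment configuration"),
  make_option("--preset", type = "character", default = NULL,
              help = paste("built-in preset: sync_plus, sync_minus, ei_plane,",
                           "mixed_facilitation, both_facilitation,",
                           "robustness, pure_tone")),
  make_option("--seed", type = "integer", default = 1,
              help = "root RNG seed [default %default]"),
  make_option("--trials", type = "integer", default = NULL,
              help = "override trials per stimulus"),
  make_option("--out", type = "character", default = "out",
              help = "output directory [default %default]")))
opt <- parse_args(parser)

if (is.null(opt$config) && is.null(opt$preset))
  stop("one of --config or --preset is required")
config <- if (!is.null(opt$config)) {
  yaml::read_yaml(opt$config)
} else {
  flutter_preset(opt$preset)
}
if (!is.null(opt$trials)) config$experiment$trials <- opt$trials

res <- run_experiment(config, opt$out, seed = opt$seed)
message("wrote: ", paste(res$paths, collapse = ", "))
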