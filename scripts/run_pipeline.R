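#!/usr/bin/env Rscript

# Thin command-line wrapper over erpoly::run_pipeline(): runs the seeded
# simulate -> sample -> scan -> blocks -> estimate -> summarize chain.
#
# Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--mode high-ld|le]
#                                  [--seed 1] [--out-dir out]
# Flags override values from --config; without --config the package
# defaults are used.

suppressPackageStartupMessages(library(erpoly))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

cfg <- if (!is.null(get_arg("--config"))) {
  read_run_config(get_arg("--config"))
} else {
  run_config()
}
mode <- get_arg("--mode")
if (!is.null(mode)) {
  cfg$mode <- switch(mode, "high-ld" = "high_ld", "le" = "linkage_equilibrium",
                     mode)
}
seed <- get_arg("--seed")
if (!is.null(seed)) cfg$seed <- as.integer(seed)
out_dir <- get_arg("--out-dir", "erpoly-run")

manifest <- run_pipeline(cfg, out_dir)
cat("run complete:", out_dir, "(config", manifest$config_hash, ")\n")
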