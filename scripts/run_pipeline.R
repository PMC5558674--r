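#!/usr/bin/env Rscript

# Thin command-line wrapper over mirlasso::run_pipeline():
#   Rscript scripts/run_pipeline.R --config run.cfg [--out-dir DIR]
# The config file is the flat key-value format documented in
# ?mirlasso::read_run_config; --out-dir overrides its out_dir key.

suppressPackageStartupMessages({
  library(optparse)
  library(mirlasso)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out-dir", type = "character", default = NULL,
              dest = "out_dir")
)))
if (is.null(opts$config)) stop("--config is required")

cfg <- read_run_config(opts$config)
if (!is.null(opts$out_dir)) cfg$out_dir <- opts$out_dir
invisible(run_pipeline(cfg))
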