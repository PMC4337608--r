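#!/usr/bin/env Rscript

# Thin command-line wrapper around the package's pipeline functions.
#
#   Rscript scripts/pipeline.R simulate --out dir [--seed N] [--config cfg.yaml]
#   Rscript scripts/pipeline.R run --in dir --out dir [--seed N] [--config cfg.yaml]
#   Rscript scripts/pipeline.R report --out dir

suppressPackageStartupMessages({
  library(optparse)
  library(neuromosaic)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run", "report")) {
  stop("usage: pipeline.R <simulate|run|report> [options]", call. = FALSE)
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = NULL, dest = "input"),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL)
)), args = args[-1])

if (cmd == "simulate") {
  sim_cfg <- if (!is.null(opts$config)) read_sim_config(opts$config) else sim_config()
  paths <- write_simulation(opts$out, sim_cfg, seed = opts$seed)
  cat("wrote", length(paths), "files to", opts$out, "\n")
} else if (cmd == "run") {
  if (is.null(opts$input)) stop("run needs --in <dir>", call. = FALSE)
  cfg <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  manifest <- run_pipeline(opts$input, opts$out, config = cfg, seed = opts$seed)
  cat("pipeline complete;", length(manifest$outputs), "outputs in", opts$out, "\n")
} else {
  make_report(opts$out)
  cat("report written to", file.path(opts$out, "report.json"), "\n")
}
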