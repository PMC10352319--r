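#!/usr/bin/env Rscript
# Thin shell entry point over nrpathways::run_pipeline():
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed N] [--outdir DIR]

suppressPackageStartupMessages(library(nrpathways))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
config <- get_arg("--config", NULL)
outdir <- get_arg("--outdir", file.path("results", "pipeline_run"))
seed <- get_arg("--seed", NULL)

cfg <- pipeline_config(config)
if (!is.null(seed)) cfg$seed <- as.integer(seed)

res <- tryCatch(run_pipeline(cfg, outdir = outdir),
                error = function(e) {
                  message(conditionMessage(e))
                  quit(status = 1L)
                })
message("outputs in: ", res$outdir)
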