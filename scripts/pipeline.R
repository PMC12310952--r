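#!/usr/bin/env Rscript
# Thin command-line wrapper over clonetrace::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R --outdir out [--seed 1] [--config cfg.yaml]
#                              [--stages simulate,filter,clones,coupling,composition]
#
# The optional YAML config carries per-stage sections (filter, clones,
# coupling, composition) plus a `sim` section passed to sim_config(); every
# omitted value keeps the package default.

suppressPackageStartupMessages({
  library(clonetrace)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL),
  make_option("--stages", type = "character", default = "all"),
  make_option("--quiet", action = "store_true", default = FALSE))))

if (is.null(opts$outdir)) stop("--outdir is required", call. = FALSE)

user <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
sim_args <- if (!is.null(user$sim)) user$sim else list()
if (!is.null(sim_args$n_progenitors)) {
  sim_args$n_progenitors <- unlist(sim_args$n_progenitors)
}
cfg <- pipeline_config(
  sim = do.call(sim_config, sim_args),
  filter = if (!is.null(user$filter)) user$filter else list(),
  clones = if (!is.null(user$clones)) user$clones else list(),
  coupling = if (!is.null(user$coupling)) user$coupling else list(),
  composition = if (!is.null(user$composition)) user$composition else list(),
  seed = opts$seed)

stages <- if (identical(opts$stages, "all")) "all" else {
  strsplit(opts$stages, ",", fixed = TRUE)[[1]]
}
invisible(run_pipeline(cfg, opts$outdir, stages = stages, quiet = opts$quiet))
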