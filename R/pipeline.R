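# End-to-end orchestration: staged execution with on-disk intermediates and
# a reproducibility manifest.

#' Pipeline configuration
#'
#' Hierarchical configuration for [run_pipeline()]. Defaults carry the
#' standard thresholds of the method: barcodes shorter than 37 bases are
#' excluded at extraction, triples need 10 reads and pairs 6 UMIs, shared
#' clones need 2 cells of each state, coupling uses 10,000 permutations,
#' and the stability statistic uses 30 PCs.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param filter List: `min_reads` (>= 1, default 10), `min_umis` (>= 1,
#'   default 6).
#' @param clones List: `cut_height` in (0, 1] (default 0.5).
#' @param coupling List: `n_perm` (default 10000), `min_cells` (default 2),
#'   `state_col` (default "subtype").
#' @param composition List: `presence_min` (default 1), `rules`
#'   (see [default_fate_rules()]), `fallback`.
#' @param seed Master seed; stage seeds derive from it and are recorded in
#'   the manifest.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            filter = list(),
                            clones = list(),
                            coupling = list(),
                            composition = list(),
                            seed = 1L) {
  filter <- modifyList(list(min_reads = 10, min_umis = 6), filter)
  clones <- modifyList(list(cut_height = 0.5), clones)
  coupling <- modifyList(list(n_perm = 10000, min_cells = 2,
                              state_col = "subtype"), coupling)
  composition <- modifyList(list(presence_min = 1,
                                 rules = default_fate_rules(),
                                 fallback = "self_renew"), composition)
  if (!is.numeric(filter$min_reads) || filter$min_reads < 1) {
    stop2("filter$min_reads must be >= 1 (the molecular threshold: ",
          "a triple needs a minimum read support, default 10 reads)")
  }
  if (!is.numeric(filter$min_umis) || filter$min_umis < 1) {
    stop2("filter$min_umis must be >= 1 (the molecular threshold: ",
          "a cell-barcode pair needs a minimum of distinct UMIs, default 6)")
  }
  if (clones$cut_height <= 0 || clones$cut_height > 1) {
    stop2("clones$cut_height must lie in (0, 1]")
  }
  check_count(coupling$n_perm, "coupling$n_perm")
  check_count(coupling$min_cells, "coupling$min_cells")
  seed <- check_count(seed, "seed", min = 0)
  sim$seed <- seed
  structure(list(sim = sim, filter = filter, clones = clones,
                 coupling = coupling, composition = composition,
                 seed = seed), class = "pipeline_config")
}

#' Run the clonal analysis pipeline
#'
#' Executes the requested stages in dependency order, reading intermediates
#' written by earlier stages from `outdir`, so partial runs resume from
#' disk. Stage outputs are plain CSV/TSV/MTX files; a JSON run manifest
#' records the resolved configuration, every seed, file checksums, and the
#' package version, sufficient to re-run bit-identically.
#'
#' Stages: `simulate` (synthetic experiment), `filter` (read/UMI filtering
#' of triples), `clones` (matrix building and clone calling), `coupling`
#' (permutation z-scores), `composition` (fate tables, restricted/mixed
#' fractions, intersections).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Character vector of stages, or `"all"`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "filter", "clones",
                                    "coupling", "composition"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) {
    stages <- c("simulate", "filter", "clones", "coupling", "composition")
  }
  known <- c("simulate", "filter", "clones", "coupling", "composition")
  if (length(bad <- setdiff(stages, known))) {
    stop2("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  log <- list()
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop2(sprintf("missing intermediate '%s': run stage '%s' first", path, stage))
    }
    path
  }
  sim_dir <- file.path(outdir, "sim")

  if ("simulate" %in% stages) {
    say("[simulate] seed ", config$seed)
    sim <- simulate_experiment(config$sim)
    write_simulation(sim, sim_dir)
    say(sprintf("[simulate] %d cells, %d clones, %d triples",
                nrow(sim$annotations), nrow(sim$truth$clones),
                nrow(sim$triples)))
    log$simulate <- list(n_cells = nrow(sim$annotations),
                         n_clones = nrow(sim$truth$clones),
                         n_triples = nrow(sim$triples))
  }

  if ("filter" %in% stages) {
    triples <- read_triples(need(file.path(sim_dir, "triples.tsv"), "simulate"))
    pairs <- filter_triples(triples, config$filter$min_reads,
                            config$filter$min_umis)
    rep <- attr(pairs, "report")
    say(sprintf("[filter] triples %d -> %d (reads >= %d); pairs %d -> %d (UMIs >= %d)",
                rep$n_triples_in, rep$n_triples_pass_reads, rep$min_reads,
                rep$n_pairs_in, rep$n_pairs_out, rep$min_umis))
    write.csv(pairs, file.path(outdir, "pairs.csv"), row.names = FALSE)
    log$filter <- rep
  }

  if ("clones" %in% stages) {
    pairs <- read.csv(need(file.path(outdir, "pairs.csv"), "filter"),
                      stringsAsFactors = FALSE)
    ann <- read.csv(need(file.path(sim_dir, "annotations.csv"), "simulate"),
                    stringsAsFactors = FALSE)
    m <- build_matrix(pairs, all_cells = ann$cell_id)
    rep <- attr(m, "report")
    say(sprintf("[clones] matrix %d cells x %d barcodes; %d barcode-less cells dropped",
                rep$n_cells, rep$n_barcodes, rep$n_dropped_cells))
    clones <- call_clones(m, config$clones$cut_height, annotations = ann)
    st <- clone_size_stats(clones)
    say(sprintf("[clones] %d clones, mean size %.2f (cut height %.2f)",
                st$n_clones, st$mean_size, config$clones$cut_height))
    write.csv(clones, file.path(outdir, "clones.csv"), row.names = FALSE)
    log$clones <- list(n_cells = rep$n_cells, n_dropped = rep$n_dropped_cells,
                       n_clones = st$n_clones, mean_size = st$mean_size,
                       cut_height = config$clones$cut_height)
  }

  if ("coupling" %in% stages) {
    clones <- read.csv(need(file.path(outdir, "clones.csv"), "clones"),
                       stringsAsFactors = FALSE)
    res <- coupling_zscores(clones, state_col = config$coupling$state_col,
                            n_perm = config$coupling$n_perm,
                            min_cells = config$coupling$min_cells,
                            seed = config$seed)
    say(sprintf("[coupling] %d states, %d permutations (seed %d)",
                length(res$states), res$n_perm, res$seed))
    write_coupling(res, file.path(outdir, "coupling"))
    log$coupling <- list(states = res$states, n_perm = res$n_perm,
                         min_cells = res$min_cells, seed = res$seed)
  }

  if ("composition" %in% stages) {
    clones <- read.csv(need(file.path(outdir, "clones.csv"), "clones"),
                       stringsAsFactors = FALSE)
    st_col <- config$coupling$state_col
    ft <- fate_table(clones, st_col)
    write.csv(as.data.frame(ft), file.path(outdir, "fate_table.csv"))
    up <- upset_intersections(clones, colnames(ft),
                              presence_min = config$composition$presence_min,
                              state_col = st_col)
    write.csv(up, file.path(outdir, "upset_intersections.csv"), row.names = FALSE)
    cls <- classify_clone_fates(clones, rules = config$composition$rules,
                                fallback = config$composition$fallback,
                                presence_min = config$composition$presence_min,
                                state_col = st_col)
    write.csv(cls, file.path(outdir, "clone_fates.csv"), row.names = FALSE)
    say(sprintf("[composition] %d clones classified into %d categories",
                nrow(cls), length(unique(cls$category))))
    log$composition <- list(n_clones = nrow(cls),
                            categories = sort(unique(cls$category)))
  }

  data_files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                        file.path(outdir, "run_manifest.json"))
  data_files <- data_files[!grepl("manifest\\.json$", data_files)]
  manifest <- list(
    package = "clonetrace",
    version = as.character(packageVersion("clonetrace")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stages = stages,
    seed = config$seed,
    config = c(list(sim = unclass_config(config$sim)),
               config[c("filter", "clones", "coupling", "composition")]),
    log = log,
    files = lapply(data_files, function(p) {
      list(path = sub(paste0("^", outdir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
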