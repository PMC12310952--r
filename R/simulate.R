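#' Default clone-fate profile for the two-progenitor cortical simulation
#'
#' Clone-level fate-category probabilities per founding progenitor subtype.
#' The defaults emulate a dual radial-glia (RGC) experiment in which the
#' two progenitor subtypes have strongly biased clonal output: `RGC_1`
#' clones are overwhelmingly neuron-linked with small minorities entering
#' either astrocyte lineage, while `RGC_2` clones are dominated by the
#' Olig2 astrocyte lineage, a large self-renewing fraction, a minority
#' linked to neurons, and none entering the S100a11 astrocyte lineage.
#'
#' @return Matrix with progenitor subtypes as rows and fate categories
#'   (`neuron`, `olig2_astro`, `s100a11_astro`, `self_renew`) as columns;
#'   rows sum to 1.
#' @export
default_fate_profile <- function() {
  m <- rbind(
    RGC_1 = c(neuron = 0.90, olig2_astro = 0.05, s100a11_astro = 0.05, self_renew = 0.00),
    RGC_2 = c(neuron = 0.16, olig2_astro = 0.50, s100a11_astro = 0.00, self_renew = 0.34))
  m
}

#' Default fate-category cell-type mixtures
#'
#' Each clone-level fate category maps to a hallmark cell type plus a mixture
#' from which the remaining member cells are drawn. The token `"founder"`
#' stands for the clone's founding progenitor subtype. A clone of size 1
#' consists of the hallmark cell alone; larger clones contain one founder
#' cell, one hallmark cell, and mixture draws for the rest — so every
#' category is identifiable from clone contents (a clone is "in the Olig2
#' lineage" because it actually produced an Olig2-lineage astrocyte).
#'
#' The default mixtures encode the lineage structure of the emulated
#' experiment: Olig2-lineage clones are restricted (progenitors plus Olig2
#' astrocytes, no neurons), S100a11-lineage clones share with neurons, and
#' self-renewing clones contain only the founder subtype.
#'
#' @return Named list of `list(hallmark =, mixture =)` per fate category.
#' @export
default_fate_mixtures <- function() {
  list(
    neuron = list(hallmark = "Neuron",
                  mixture = c(Neuron = 0.70, founder = 0.30)),
    olig2_astro = list(hallmark = "Astro_Olig2",
                       mixture = c(Astro_Olig2 = 0.55, founder = 0.45)),
    s100a11_astro = list(hallmark = "Astro_S100a11",
                         mixture = c(Astro_S100a11 = 0.50, founder = 0.30, Neuron = 0.20)),
    self_renew = list(hallmark = "founder",
                      mixture = c(founder = 1)))
}

#' Configuration of a synthetic lineage-barcoding experiment
#'
#' Bundles and validates all generative parameters. Defaults emulate a
#' transposon lineage-tracing experiment in developing mouse cortex: a
#' barcode library of 1e5 variants, multiple integrations per founding
#' progenitor, clones averaging 4.5 cells, barcode recovery in 75% of
#' cells, and the biased fate profile of [default_fate_profile()].
#'
#' @param n_progenitors Named integer vector: founding progenitors (= clones)
#'   per progenitor subtype.
#' @param fate_profile Row-stochastic matrix of clone fate-category
#'   probabilities per subtype (rows = subtypes of `n_progenitors`).
#' @param fate_mixtures Per-category hallmark/mixture list; see
#'   [default_fate_mixtures()].
#' @param clone_size_dist [dist_spec()] for cells per clone (default
#'   zero-truncated Poisson with mean 4.5).
#' @param barcode_library_size Number of distinct barcodes in the library.
#' @param barcode_length Barcode length in bases (>= 37 so the read-length
#'   filter is exercisable).
#' @param integrations_dist [dist_spec()] for integrations per founder
#'   (default zero-truncated Poisson with mean 2).
#' @param barcode_recovery_rate Probability that a cell yields any barcode
#'   triple at all.
#' @param umi_per_pair_dist [dist_spec()] for UMIs per recovered
#'   cell-barcode pair.
#' @param reads_per_triple_dist [dist_spec()] for reads supporting one
#'   cell-UMI-barcode triple. The default places roughly 15-20% of triples
#'   below the 10-read threshold, so the filters do real work.
#' @param n_genes,n_marker_genes_per_type,expression_effect_size,dispersion,base_mean
#'   Expression model: negative-binomial counts with `n_marker_genes_per_type`
#'   marker genes per cell type elevated `expression_effect_size`-fold;
#'   `dispersion` is the NB shape, `base_mean` the log-normal median of
#'   per-gene baseline means.
#' @param timepoint,dataset Constant annotation labels.
#' @param seed Integer seed; fixing it makes every emitted table
#'   reproducible.
#' @return Object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_progenitors = c(RGC_1 = 20, RGC_2 = 20), seed = 1)
#' sim <- simulate_experiment(cfg)
#' head(sim$triples)
#' @export
sim_config <- function(n_progenitors = c(RGC_1 = 250, RGC_2 = 250),
                       fate_profile = default_fate_profile(),
                       fate_mixtures = default_fate_mixtures(),
                       clone_size_dist = dist_spec("ztpois", mean = 4.5),
                       barcode_library_size = 100000,
                       barcode_length = 40,
                       integrations_dist = dist_spec("ztpois", mean = 2),
                       barcode_recovery_rate = 0.75,
                       umi_per_pair_dist = dist_spec("ztnbinom", mean = 15, size = 15),
                       reads_per_triple_dist = dist_spec("ztnbinom", mean = 24, size = 2),
                       n_genes = 1000,
                       n_marker_genes_per_type = 25,
                       expression_effect_size = 3,
                       dispersion = 2,
                       base_mean = 0.3,
                       timepoint = "P7",
                       dataset = "sim1",
                       seed = 1L) {
  if (is.null(names(n_progenitors)) || any(!nzchar(names(n_progenitors)))) {
    stop2("`n_progenitors` must be a named vector of progenitor subtypes")
  }
  n_progenitors <- vapply(n_progenitors, check_count, integer(1),
                          name = "n_progenitors")
  if (!is.matrix(fate_profile) ||
      !setequal(rownames(fate_profile), names(n_progenitors))) {
    stop2("`fate_profile` rows must match the subtypes of `n_progenitors`")
  }
  fate_profile <- fate_profile[names(n_progenitors), , drop = FALSE]
  for (s in rownames(fate_profile)) {
    fate_profile[s, ] <- check_prob_vector(fate_profile[s, ],
                                           paste0("fate_profile[", s, ",]"))
  }
  if (!all(colnames(fate_profile) %in% names(fate_mixtures))) {
    stop2("every fate category needs an entry in `fate_mixtures`")
  }
  for (cat in names(fate_mixtures)) {
    fm <- fate_mixtures[[cat]]
    fm$mixture <- check_prob_vector(fm$mixture,
                                    paste0("fate_mixtures$", cat, "$mixture"))
    fate_mixtures[[cat]] <- fm
  }
  for (d in c("clone_size_dist", "integrations_dist", "umi_per_pair_dist",
              "reads_per_triple_dist")) {
    if (!inherits(get(d), "dist_spec")) stop2(sprintf("`%s` must be a dist_spec", d))
  }
  cfg <- list(
    n_progenitors = n_progenitors,
    fate_profile = fate_profile,
    fate_mixtures = fate_mixtures,
    clone_size_dist = clone_size_dist,
    barcode_library_size = check_count(barcode_library_size, "barcode_library_size"),
    barcode_length = check_count(barcode_length, "barcode_length", min = 1),
    integrations_dist = integrations_dist,
    barcode_recovery_rate = check_prob(barcode_recovery_rate, "barcode_recovery_rate"),
    umi_per_pair_dist = umi_per_pair_dist,
    reads_per_triple_dist = reads_per_triple_dist,
    n_genes = check_count(n_genes, "n_genes"),
    n_marker_genes_per_type = check_count(n_marker_genes_per_type, "n_marker_genes_per_type"),
    expression_effect_size = as.numeric(expression_effect_size),
    dispersion = as.numeric(dispersion),
    base_mean = as.numeric(base_mean),
    timepoint = as.character(timepoint),
    dataset = as.character(dataset),
    seed = check_count(seed, "seed", min = 0))
  if (cfg$expression_effect_size <= 0 || cfg$dispersion <= 0 || cfg$base_mean <= 0) {
    stop2("expression parameters must be positive")
  }
  structure(cfg, class = "sim_config")
}

# map "founder" tokens of a mixture/hallmark to the concrete subtype
resolve_types <- function(x, founder) {
  if (is.character(x)) {
    return(ifelse(x == "founder", founder, x))
  }
  nm <- names(x)
  nm[nm == "founder"] <- founder
  # merge duplicated names (e.g. founder already present explicitly)
  tapply(unname(x), nm, sum)
}

coarse_type <- function(subtype) {
  ifelse(grepl("^RGC", subtype), "RGC",
         ifelse(grepl("^Astro", subtype), "Astrocyte", subtype))
}

sim_impl <- function(config, null_types = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    subtypes <- names(config$n_progenitors)
    n_clones <- sum(config$n_progenitors)
    founder <- rep(subtypes, config$n_progenitors)
    clone_id <- seq_len(n_clones)

    # clone-level draws
    fate <- character(n_clones)
    for (s in subtypes) {
      idx <- which(founder == s)
      fate[idx] <- sample(colnames(config$fate_profile), length(idx),
                          replace = TRUE, prob = config$fate_profile[s, ])
    }
    size <- sample_dist(config$clone_size_dist, n_clones)
    k_int <- sample_dist(config$integrations_dist, n_clones)

    # integration barcodes: indices drawn with replacement from the library,
    # so two clones collide at the analytic birthday rate
    bc_idx <- lapply(k_int, function(k) {
      sort(unique(sample.int(config$barcode_library_size, k, replace = TRUE)))
    })
    used <- sort(unique(unlist(bc_idx)))
    seqs <- random_dna(length(used), config$barcode_length)
    bc_seq_of <- setNames(seqs, used)

    # member cell types per clone
    n_cells <- sum(size)
    cell_clone <- rep.int(clone_id, size)
    cell_type <- character(n_cells)
    pos <- 1L
    for (i in clone_id) {
      fm <- config$fate_mixtures[[fate[i]]]
      hall <- resolve_types(fm$hallmark, founder[i])
      mix <- resolve_types(fm$mixture, founder[i])
      k <- size[i]
      types <- if (k == 1L) hall else {
        c(founder[i], hall,
          if (k > 2L) sample(names(mix), k - 2L, replace = TRUE, prob = mix))
      }
      cell_type[pos:(pos + k - 1L)] <- types
      pos <- pos + k
    }
    cell_id <- pad_ids("cell", n_cells)

    if (null_types) {
      # break every clone-type association: redraw types i.i.d. from the
      # pooled frequencies of the generated experiment
      freq <- table(cell_type)
      cell_type <- sample(names(freq), n_cells, replace = TRUE,
                          prob = as.numeric(freq))
    }

    # barcode capture
    recovered <- runif(n_cells) < config$barcode_recovery_rate
    rec_idx <- which(recovered)
    pair_cell <- integer(0); pair_bc <- integer(0)
    for (ci in rec_idx) {
      b <- bc_idx[[cell_clone[ci]]]
      pair_cell <- c(pair_cell, rep.int(ci, length(b)))
      pair_bc <- c(pair_bc, b)
    }
    n_pairs <- length(pair_cell)
    umis_per_pair <- sample_dist(config$umi_per_pair_dist, n_pairs)
    n_triples <- sum(umis_per_pair)
    tri_pair <- rep.int(seq_len(n_pairs), umis_per_pair)
    # distinct UMIs within each pair: indices sampled without replacement
    # from the 4^12 UMI space, rendered as DNA 12-mers
    umi_str <- character(n_triples)
    off <- 0L
    for (p in seq_len(n_pairs)) {
      m <- umis_per_pair[p]
      umi_str[off + seq_len(m)] <- int_to_dna(sample.int(4^12, m) - 1L, 12L)
      off <- off + m
    }
    reads <- sample_dist(config$reads_per_triple_dist, n_triples)
    triples <- data.frame(
      cell_bc = cell_id[pair_cell[tri_pair]],
      umi = umi_str,
      lineage_bc = unname(bc_seq_of[as.character(pair_bc[tri_pair])]),
      reads = reads,
      stringsAsFactors = FALSE)
    triples <- triples[order(triples$cell_bc, triples$lineage_bc, triples$umi), ,
                       drop = FALSE]
    rownames(triples) <- NULL

    # expression: NB counts with marker elevation per cell type
    all_types <- sort(unique(c(
      subtypes,
      unlist(lapply(config$fate_mixtures, function(fm) {
        c(fm$hallmark, names(fm$mixture))
      })))))
    all_types <- setdiff(all_types, "founder")
    G <- config$n_genes
    gene_id <- pad_ids("gene", G)
    base <- rlnorm(G, meanlog = log(config$base_mean), sdlog = 1)
    marker_of <- rep(NA_character_, G)
    nm <- config$n_marker_genes_per_type
    need <- nm * length(all_types)
    if (need > G) stop2("n_genes too small for the requested marker genes")
    marker_of[seq_len(need)] <- rep(all_types, each = nm)
    counts <- matrix(0L, nrow = G, ncol = n_cells,
                     dimnames = list(gene_id, cell_id))
    for (ty in all_types) {
      cols <- which(cell_type == ty)
      if (!length(cols)) next
      mu <- base
      mu[which(marker_of == ty)] <- mu[which(marker_of == ty)] * config$expression_effect_size
      counts[, cols] <- rnbinom(G * length(cols), size = config$dispersion,
                                mu = rep(mu, times = length(cols)))
    }
    expression <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "CsparseMatrix"), "generalMatrix")
    attr(expression, "layer") <- "raw"

    annotations <- data.frame(
      cell_id = cell_id,
      cell_type = coarse_type(cell_type),
      subtype = cell_type,
      timepoint = config$timepoint,
      dataset = config$dataset,
      stringsAsFactors = FALSE)

    truth_cells <- data.frame(
      cell_id = cell_id,
      clone_id = cell_clone,
      founder_subtype = founder[cell_clone],
      subtype = cell_type,
      recovered = recovered,
      timepoint = config$timepoint,
      dataset = config$dataset,
      stringsAsFactors = FALSE)
    truth_clones <- data.frame(
      clone_id = clone_id,
      founder_subtype = founder,
      fate_category = fate,
      size = size,
      n_integrations = vapply(bc_idx, length, integer(1)),
      barcodes = vapply(bc_idx, function(b) {
        paste(bc_seq_of[as.character(b)], collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE)

    structure(list(
      triples = triples,
      annotations = annotations,
      expression = expression,
      truth = list(cells = truth_cells, clones = truth_clones),
      config = config,
      null = null_types), class = "clonetrace_sim")
  })
}

#' Simulate a lineage-barcoding experiment with known clonal ground truth
#'
#' Generates clones founded by progenitors of configurable subtypes, each
#' founder drawing one or more integration barcodes (with replacement) from a
#' finite library; every member cell inherits the founder's barcode set.
#' Clone fates are drawn at the clone level from the subtype's fate profile
#' and member cell types from the category's mixture. Barcode capture is
#' lossy (`barcode_recovery_rate`), and molecule-level noise enters through
#' the UMI and read-count distributions, so downstream filtering is
#' exercised realistically. Expression counts are negative binomial with
#' cell-type marker elevation.
#'
#' @param config A [sim_config()].
#' @return A `clonetrace_sim` list with elements `triples` (data frame:
#'   `cell_bc`, `umi`, `lineage_bc`, `reads`), `annotations` (cell-level
#'   labels), `expression` (sparse gene x cell counts, layer `"raw"`), and
#'   `truth` (`$cells`, `$clones` ground-truth tables).
#' @seealso [simulate_null()] for the matched no-association control.
#' @export
simulate_experiment <- function(config) sim_impl(config, null_types = FALSE)

#' Simulate the matched null experiment (no clone-fate association)
#'
#' Identical generative process to [simulate_experiment()] except that each
#' cell's type is redrawn i.i.d. from the pooled type frequencies, breaking
#' every association between clone membership and cell type. Used to
#' calibrate the permutation-null coupling statistics: z-scores computed on
#' this output should average ~0 with unit variance.
#'
#' @inheritParams simulate_experiment
#' @return As [simulate_experiment()].
#' @export
simulate_null <- function(config) sim_impl(config, null_types = TRUE)

# base-4 rendering of integers as DNA k-mers (0 = A...A)
int_to_dna <- function(x, width) {
  alphabet <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(x), ncol = width)
  for (j in width:1) {
    out[, j] <- alphabet[x %% 4 + 1]
    x <- x %/% 4
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

#' @export
print.clonetrace_sim <- function(x, ...) {
  cat(sprintf("<clonetrace_sim%s: %d cells, %d clones, %d triples, %d genes>\n",
              if (isTRUE(x$null)) " (null)" else "",
              nrow(x$annotations), nrow(x$truth$clones), nrow(x$triples),
              nrow(x$expression)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the simulator outputs in plain interchange formats: triples as TSV,
#' annotations and truth tables as CSV, expression as MatrixMarket (`.mtx`)
#' plus row/column name files, and a JSON run manifest echoing the full
#' configuration and file checksums.
#'
#' @param sim A `clonetrace_sim`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "clonetrace_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    triples = file.path(dir, "triples.tsv"),
    annotations = file.path(dir, "annotations.csv"),
    truth_cells = file.path(dir, "truth_cells.csv"),
    truth_clones = file.path(dir, "truth_clones.csv"),
    expression = file.path(dir, "expression.mtx"),
    genes = file.path(dir, "genes.txt"),
    cells = file.path(dir, "cells.txt"))
  write_triples(sim$triples, paths$triples)
  write.csv(sim$annotations, paths$annotations, row.names = FALSE)
  write.csv(sim$truth$cells, paths$truth_cells, row.names = FALSE)
  write.csv(sim$truth$clones, paths$truth_clones, row.names = FALSE)
  Matrix::writeMM(sim$expression, paths$expression)
  writeLines(rownames(sim$expression), paths$genes)
  writeLines(colnames(sim$expression), paths$cells)
  manifest <- list(
    config = unclass_config(sim$config),
    null = isTRUE(sim$null),
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# config as plain JSON-serializable list
unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$fate_profile <- as.data.frame(out$fate_profile)
  out$fate_mixtures <- lapply(out$fate_mixtures, function(fm) {
    list(hallmark = fm$hallmark, mixture = as.list(fm$mixture))
  })
  for (d in c("clone_size_dist", "integrations_dist", "umi_per_pair_dist",
              "reads_per_triple_dist")) {
    out[[d]] <- unclass(out[[d]])
  }
  out
}

#' Write simulated barcode reads as FASTQ
#'
#' Optional read-level emission for testing the extraction path: each triple
#' expands to `reads` identical records whose name carries the cell barcode
#' and UMI (`cell:umi`, the convention of [extract_barcodes()]) and whose
#' sequence is `flank5 | lineage barcode | flank3`.
#'
#' @param sim A `clonetrace_sim`.
#' @param path Output FASTQ path; `.gz` suffix writes gzip.
#' @param flank5,flank3 Constant adapter sequences around the barcode.
#' @param max_reads_per_triple Cap on per-triple read expansion (keeps test
#'   files small without changing which triples exist).
#' @return Invisibly, the number of records written.
#' @export
write_sim_fastq <- function(sim, path, flank5 = "ACGTACGTAC",
                            flank3 = "GTACGTACGT",
                            max_reads_per_triple = Inf) {
  stopifnot(inherits(sim, "clonetrace_sim"))
  tr <- sim$triples
  nrep <- pmin(tr$reads, max_reads_per_triple)
  idx <- rep.int(seq_len(nrow(tr)), nrep)
  name <- paste0("@", tr$cell_bc[idx], ":", tr$umi[idx])
  seqs <- paste0(flank5, tr$lineage_bc[idx], flank3)
  qual <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rbind(name, seqs, "+", qual), con)
  invisible(length(idx))
}
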