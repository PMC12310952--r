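# Extraction, the read/UMI filters, and matrix construction.

fq_record <- function(name, seq) c(paste0("@", name), seq, "+", strrep("I", nchar(seq)))

write_fq <- function(lines, path = withr::local_tempfile(fileext = ".fastq",
                                                         .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

test_that("inserts shorter than the length cutoff are excluded", {
  bc36 <- strrep("A", 36); bc37 <- strrep("G", 37)
  fq <- write_fq(c(fq_record("c1:u1", paste0("TTTTT", bc36, "CCCCC")),
                   fq_record("c1:u2", paste0("TTTTT", bc37, "CCCCC"))))
  tr <- extract_barcodes(fq, "TTTTT", "CCCCC", min_len = 37, whitelist = "c1")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$lineage_bc, bc37)
  expect_equal(attr(tr, "report")$n_short_insert, 1)
})

test_that("identical observations aggregate into read counts and flankless reads are skipped", {
  bc <- strrep("ACGT", 10)
  fq <- write_fq(c(fq_record("c1:u1", paste0("TTTTT", bc, "CCCCC")),
                   fq_record("c1:u1", paste0("TTTTT", bc, "CCCCC")),
                   fq_record("c2:u9", paste0("GGGGG", bc, "CCCCC")),  # no 5' flank
                   fq_record("cX:u2", paste0("TTTTT", bc, "CCCCC")))) # off whitelist
  tr <- extract_barcodes(fq, "TTTTT", "CCCCC", whitelist = c("c1", "c2"))
  expect_equal(tr, data.frame(cell_bc = "c1", umi = "u1", lineage_bc = bc,
                              reads = 2L, stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  rep <- attr(tr, "report")
  expect_equal(rep$n_no_flank, 1)
  expect_equal(rep$n_off_whitelist, 1)
})

test_that("malformed FASTQ reports the record index", {
  path <- write_fq(c("@c1:u1", "ACGT", "+", "IIII", "@c2:u2", "ACGT"))
  expect_error(extract_barcodes(path, "A", "T", whitelist = "c1"),
               "record 2")
})

test_that("simulated FASTQ round-trips to the simulator's own triples", {
  sim <- simulate_experiment(small_config(6, 6, seed = 8))
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_sim_fastq(sim, fq, flank5 = "ACGTACGTAC", flank3 = "GTACGTACGT",
                  max_reads_per_triple = 3)
  tr <- extract_barcodes(fq, "ACGTACGTAC", "GTACGTACGT",
                         whitelist = sim$annotations$cell_id)
  truth <- sim$triples
  truth$reads <- pmin(truth$reads, 3L)
  expect_equal(tr, truth, ignore_attr = TRUE)
})

test_that("read and UMI thresholds bind exactly at their boundaries", {
  mk <- function(cell, bc, n_umi, reads) {
    data.frame(cell_bc = cell, umi = sprintf("%s_%s_u%d", cell, bc, seq_len(n_umi)),
               lineage_bc = bc, reads = reads, stringsAsFactors = FALSE)
  }
  triples <- rbind(
    mk("C1", "B1", 6, 10),     # exactly at both thresholds: kept
    mk("C1", "B2", 5, 1000),   # deep reads but only 5 UMIs: dropped
    mk("C2", "B1", 8, 9))      # all triples one read short: dropped
  out <- filter_triples(triples, min_reads = 10, min_umis = 6)
  expect_equal(out$cell_bc, "C1")
  expect_equal(out$lineage_bc, "B1")
  expect_equal(out$umi_count, 6L)
  rep <- attr(out, "report")
  expect_equal(rep$n_triples_in, 19)
  expect_equal(rep$n_triples_pass_reads, 11)
  expect_equal(rep$n_pairs_out, 1)

  all9 <- mk("C3", "B3", 10, 9)
  out2 <- filter_triples(all9)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "report")$n_pairs_in, 0)
})

test_that("empty input yields an empty table plus report, not an error", {
  out <- filter_triples(clonetrace:::empty_triples())
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "report")$n_triples_in, 0)
})

test_that("filters are monotone in both thresholds", {
  sim <- simulate_experiment(small_config(25, 25, seed = 5))
  base <- nrow(filter_triples(sim$triples, 10, 6))
  for (mr in c(1, 5, 10, 20)) {
    for (mu in c(1, 3, 6, 9)) {
      n <- nrow(filter_triples(sim$triples, mr, mu))
      if (mr >= 10 && mu >= 6) expect_lte(n, base)
      if (mr <= 10 && mu <= 6) expect_gte(n, base)
    }
  }
})

test_that("aggregation and filtering are order-independent", {
  sim <- simulate_experiment(small_config(15, 15, seed = 9))
  shuffled <- sim$triples[sample(nrow(sim$triples)), ]
  expect_equal(filter_triples(sim$triples), filter_triples(shuffled),
               ignore_attr = TRUE)
})

test_that("unaggregated triples are rejected", {
  dup <- data.frame(cell_bc = "C1", umi = "u1", lineage_bc = "B1",
                    reads = c(5L, 7L))
  expect_error(filter_triples(dup), "not aggregated")
})

test_that("matrix construction is exact, ordered, and reports drops", {
  pairs <- data.frame(cell_bc = c("c2", "c1", "c1"),
                      lineage_bc = c("b1", "b2", "b1"),
                      stringsAsFactors = FALSE)
  m <- build_matrix(pairs, all_cells = c("c1", "c2", "c3"))
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m), c("c1", "c2"))
  expect_equal(sum(m), 3)
  expect_equal(attr(m, "report")$dropped_cells, "c3")
  expect_error(build_matrix(pairs[c(1, 1), ]), "duplicate")
})

test_that("noise-free simulation reproduces the truth incidence exactly", {
  cfg <- small_config(10, 10, seed = 21,
                      barcode_recovery_rate = 1.0,
                      umi_per_pair_dist = dist_spec("fixed", value = 8),
                      reads_per_triple_dist = dist_spec("fixed", value = 20))
  sim <- simulate_experiment(cfg)
  m <- build_matrix(filter_triples(sim$triples))
  truth_sets <- strsplit(sim$truth$clones$barcodes, ";", fixed = TRUE)
  for (i in seq_len(nrow(sim$truth$cells))) {
    cell <- sim$truth$cells$cell_id[i]
    expect_setequal(colnames(m)[m[cell, ] == 1],
                    truth_sets[[sim$truth$cells$clone_id[i]]])
  }
})

test_that("matrix write/read round-trips in both formats", {
  sim <- simulate_experiment(small_config(8, 8, seed = 13))
  m <- build_matrix(filter_triples(sim$triples))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".mtx")
  write_matrix(m, p1); write_matrix(m, p2)
  expect_equal(as.matrix(read_matrix(p1)), as.matrix(m), ignore_attr = TRUE)
  expect_equal(as.matrix(read_matrix(p2)), as.matrix(m), ignore_attr = TRUE)
})
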