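# Generator: degenerate cases, analytic collision rate, target emulation,
# determinism, and null construction.

test_that("noise-free degenerate config gives one fully shared barcode", {
  cfg <- sim_config(
    n_progenitors = c(RGC_1 = 1),
    fate_profile = matrix(c(1, 0, 0, 0), 1,
                          dimnames = list("RGC_1",
                                          c("neuron", "olig2_astro",
                                            "s100a11_astro", "self_renew"))),
    clone_size_dist = dist_spec("fixed", value = 3),
    integrations_dist = dist_spec("fixed", value = 1),
    barcode_recovery_rate = 1.0,
    seed = 4)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$annotations), 3)
  expect_equal(length(unique(sim$triples$lineage_bc)), 1)
  expect_setequal(unique(sim$triples$cell_bc), sim$annotations$cell_id)
})

test_that("barcode collisions between founders occur at the birthday rate", {
  # 1,000 founders, 1 integration each, library 100,000: expected number of
  # colliding founder pairs ~ choose(1000,2)/1e5 ~ 5; Poisson 99% interval
  lam <- choose(1000, 2) / 1e5
  lo <- qpois(0.005, lam); hi <- qpois(0.995, lam)
  cfg <- sim_config(n_progenitors = c(RGC_1 = 500, RGC_2 = 500),
                    integrations_dist = dist_spec("fixed", value = 1),
                    clone_size_dist = dist_spec("fixed", value = 1),
                    n_genes = 10, n_marker_genes_per_type = 1,
                    seed = 10)
  sim <- simulate_experiment(cfg)
  bcs <- sim$truth$clones$barcodes
  tab <- table(bcs)
  n_coll_pairs <- sum(choose(tab, 2))
  expect_gte(n_coll_pairs, lo)
  expect_lte(n_coll_pairs, hi)
})

test_that("default clone sizes emulate the 4.5-cell average", {
  cfg <- sim_config(n_progenitors = c(RGC_1 = 500, RGC_2 = 500),
                    n_genes = 10, n_marker_genes_per_type = 1, seed = 2)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth$clones), 1000)
  expect_lt(abs(mean(sim$truth$clones$size) - 4.5), 0.3)
})

test_that("cells with at least one triple track the recovery rate", {
  cfg <- small_config(150, 150, seed = 6)
  sim <- simulate_experiment(cfg)
  n <- nrow(sim$annotations)
  frac <- length(unique(sim$triples$cell_bc)) / n
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(frac - 0.75), 4 * se)
  # ground truth records exactly which cells were recovered
  expect_setequal(unique(sim$triples$cell_bc),
                  sim$truth$cells$cell_id[sim$truth$cells$recovered])
})

test_that("fixing the seed reproduces every table exactly", {
  a <- simulate_experiment(small_config(10, 10, seed = 99))
  b <- simulate_experiment(small_config(10, 10, seed = 99))
  expect_identical(a$triples, b$triples)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  expect_identical(as.matrix(a$expression), as.matrix(b$expression))
  c <- simulate_experiment(small_config(10, 10, seed = 100))
  expect_false(identical(a$triples, c$triples))
})

test_that("simulation does not disturb the session RNG stream", {
  set.seed(123); x1 <- runif(3)
  set.seed(123); invisible(simulate_experiment(small_config(5, 5, seed = 1)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("clone fate frequencies converge to the configured profile", {
  # pooled over seeds, chi-square GOF per founder subtype, alpha = 0.01
  cnt1 <- cnt2 <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_progenitors = c(RGC_1 = 250, RGC_2 = 250),
                      n_genes = 10, n_marker_genes_per_type = 1, seed = s)
    tc <- simulate_experiment(cfg)$truth$clones
    f1 <- table(factor(tc$fate_category[tc$founder_subtype == "RGC_1"],
                       levels = colnames(default_fate_profile())))
    f2 <- table(factor(tc$fate_category[tc$founder_subtype == "RGC_2"],
                       levels = colnames(default_fate_profile())))
    cnt1 <- cnt1 + f1; cnt2 <- cnt2 + f2
  }
  p <- default_fate_profile()
  p1 <- chisq.test(cnt1[p["RGC_1", ] > 0], p = p["RGC_1", p["RGC_1", ] > 0])$p.value
  p2 <- chisq.test(cnt2[p["RGC_2", ] > 0], p = p["RGC_2", p["RGC_2", ] > 0])$p.value
  expect_gt(p1, 0.01)
  expect_gt(p2, 0.01)
})

test_that("null simulator breaks the clone-type association", {
  sim <- simulate_null(small_config(100, 100, seed = 12))
  cl <- truth_clone_table(sim)
  # type composition of large clones is indistinguishable from the pooled
  # margin: chi-square independence on clone x type counts
  ft <- fate_table(cl)
  big <- ft[rowSums(ft) >= 4, ]
  expect_gt(suppressWarnings(chisq.test(big))$p.value, 0.001)
  # determinism holds for the null generator too
  sim2 <- simulate_null(small_config(100, 100, seed = 12))
  expect_identical(sim$annotations, sim2$annotations)
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(sim_config(n_progenitors = c(RGC_1 = 0)), "integer >= 1")
  expect_error(sim_config(n_progenitors = c(5)), "named")
  bad <- default_fate_profile(); bad["RGC_1", 1] <- 0.5
  expect_error(sim_config(fate_profile = bad), "summing to 1")
  expect_error(sim_config(barcode_recovery_rate = 1.2), "probability")
  expect_error(dist_spec("ztpois", mean = 0.5), "exceed 1")
})

test_that("simulation round-trips through disk and the manifest checksums match", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(small_config(8, 8, seed = 3))
  man <- write_simulation(sim, dir)
  tr <- read_triples(file.path(dir, "triples.tsv"))
  expect_equal(tr, sim$triples)
  m <- Matrix::readMM(file.path(dir, "expression.mtx"))
  expect_equal(unname(as.matrix(m)), unname(as.matrix(sim$expression)))
  expect_equal(readLines(file.path(dir, "genes.txt")), rownames(sim$expression))
  expect_true(all(vapply(man$files, function(f) {
    file.exists(file.path(dir, f$path))
  }, logical(1))))
})
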