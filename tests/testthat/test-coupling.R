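# Shared-clone counts, permutation z-scores against exhaustive enumeration,
# null behaviour, and the z-row correlation structure.

toy_clones <- function() {
  # 6 clones over states A/B/C with known shared structure
  data.frame(
    cell_id = sprintf("c%02d", 1:22),
    clone_id = rep(1:6, c(4, 4, 3, 4, 3, 4)),
    subtype = c("A", "A", "B", "B",   # clone 1: shared A-B
                "A", "B", "B", "B",   # clone 2: only 1 A -> not shared
                "A", "A", "A",        # clone 3: self A
                "C", "C", "A", "A",   # clone 4: shared A-C
                "B", "C", "C",        # clone 5: 1 B only
                "B", "B", "C", "C"),  # clone 6: shared B-C
    stringsAsFactors = FALSE)
}

test_that("shared-clone counts follow the minimum-cells rule", {
  cl <- data.frame(cell_id = sprintf("c%d", 1:8),
                   clone_id = c(1, 1, 1, 1, 2, 2, 2, 2),
                   subtype = c("A", "A", "B", "B", "A", "B", "B", "B"))
  expect_equal(shared_clone_count(cl, "A", "B"), 1L)
  expect_equal(shared_clone_count(cl, "A", "A"), 1L)  # self-coupling
  expect_equal(shared_clone_count(cl, "B", "B"), 2L)
  expect_equal(shared_clone_count(cl[0, ], "A", "B"), 0L)
  expect_error(shared_clone_count(cl, "A", "Z"), "known states")
})

test_that("shared counts equal an exhaustive per-clone scan on the toy table", {
  cl <- toy_clones()
  for (a in c("A", "B", "C")) {
    for (b in c("A", "B", "C")) {
      expect_equal(shared_clone_count(cl, a, b),
                   oracle_shared_count(cl, a, b),
                   info = paste(a, b))
    }
  }
})

test_that("permutation moments match full enumeration on tiny instances", {
  # <= 7 cells: mu and sigma from all 7! label orderings are exact
  cl <- data.frame(cell_id = sprintf("c%d", 1:7),
                   clone_id = c(1, 1, 1, 2, 2, 3, 3),
                   subtype = c("A", "A", "B", "A", "B", "B", "A"))
  lab <- cl$subtype
  perms <- all_permutations(7)
  states <- sort(unique(lab))
  clone_idx <- split(seq_len(7), cl$clone_id)
  exact <- array(0, c(2, 2, nrow(perms)))
  for (k in seq_len(nrow(perms))) {
    pl <- lab[perms[k, ]]
    pres <- vapply(clone_idx, function(ix) {
      c(sum(pl[ix] == states[1]) >= 2, sum(pl[ix] == states[2]) >= 2)
    }, logical(2))
    exact[, , k] <- tcrossprod(pres * 1)
  }
  mu_exact <- apply(exact, c(1, 2), mean)
  sd_exact <- apply(exact, c(1, 2), function(v) sqrt(mean((v - mean(v))^2)))

  res <- coupling_zscores(cl, n_perm = 10000, min_cells = 2, seed = 77)
  # Monte-Carlo standard errors: sd/sqrt(n) for mu, sd/sqrt(2n) for sigma
  for (i in 1:2) {
    for (j in 1:2) {
      se_mu <- sd_exact[i, j] / sqrt(10000)
      expect_lt(abs(res$mu[i, j] - mu_exact[i, j]), 3 * se_mu + 1e-12)
      se_sd <- sd_exact[i, j] / sqrt(2 * 10000)
      expect_lt(abs(res$sigma[i, j] - sd_exact[i, j]), 3 * se_sd + 1e-12)
    }
  }
})

test_that("z-scores are invariant to clone relabeling and row order", {
  cl <- toy_clones()
  res1 <- coupling_zscores(cl, n_perm = 500, seed = 5)
  relab <- cl
  relab$clone_id <- c(60, 10, 40, 20, 50, 30)[relab$clone_id]
  relab <- relab[rev(seq_len(nrow(relab))), ]
  res2 <- coupling_zscores(relab, n_perm = 500, seed = 5)
  expect_equal(res1$Z, res2$Z)
  expect_equal(res1$observed, res2$observed)
})

test_that("injecting truly shared clones never decreases the pair z-score", {
  base <- toy_clones()
  res0 <- coupling_zscores(base, n_perm = 1000, seed = 9)
  z_prev <- res0$Z["A", "B"]
  extra <- base
  for (k in 1:3) {
    inject <- data.frame(cell_id = sprintf("x%d_%d", k, 1:4),
                         clone_id = 100 + k,
                         subtype = c("A", "A", "B", "B"),
                         stringsAsFactors = FALSE)
    extra <- rbind(extra, inject)
    z_now <- coupling_zscores(extra, n_perm = 1000, seed = 9)$Z["A", "B"]
    expect_gte(z_now, z_prev - 1e-9)
    z_prev <- z_now
  }
})

test_that("degenerate permutation cells are masked with zero z", {
  # state D has a single cell: no permutation can yield >= 2 D cells in a
  # clone, so sigma = 0 for every D pair (and its constant z-row makes the
  # correlations partially undefined, which warns)
  cl <- rbind(toy_clones(),
              data.frame(cell_id = "c99", clone_id = 7, subtype = "D"))
  expect_warning(res <- coupling_zscores(cl, n_perm = 200, seed = 3),
                 "undefined")
  expect_true(all(res$mask["D", ]))
  expect_true(all(res$Z["D", ] == 0))
  expect_false(any(res$mask[c("A", "B"), c("A", "B")]))
})

test_that("states with zero cells are dropped with a warning", {
  cl <- toy_clones()
  cl$subtype <- factor(cl$subtype, levels = c("A", "B", "C", "Ghost"))
  expect_warning(res <- coupling_zscores(cl, n_perm = 100, seed = 1),
                 "zero cells")
  expect_setequal(res$states, c("A", "B", "C"))
})

test_that("z-row correlations: identical rows give 1, orthogonal give 0", {
  # symmetric Z whose rows a and b agree on every shared (non-a, non-b)
  # column -> correlation exactly 1
  st <- c("a", "b", "x", "y", "z")
  Z <- matrix(0, 5, 5, dimnames = list(st, st))
  Z["a", c("x", "y", "z")] <- Z["b", c("x", "y", "z")] <- c(1, 2, 5)
  Z["a", "b"] <- 7
  Z <- Z + t(Z)
  cc <- coupling_correlations(Z)
  expect_equal(cc$correlations["a", "b"], 1.0)
  # rows a and b centered and orthogonal on the shared columns -> 0
  Z2 <- matrix(0, 5, 5, dimnames = list(st, st))
  Z2["a", c("x", "y", "z")] <- c(1, 0, -1)
  Z2["b", c("x", "y", "z")] <- c(1, -2, 1)
  Z2 <- Z2 + t(Z2)
  # rows x, y, z are constant over their retained entries here, which
  # legitimately warns; only the a-b orthogonality is under test
  cc2 <- suppressWarnings(coupling_correlations(Z2))
  expect_lt(abs(cc2$correlations["a", "b"]), 1e-12)
})

test_that("constant z-rows yield masked correlations with a warning", {
  st <- letters[1:4]
  Z <- matrix(0, 4, 4, dimnames = list(st, st))
  Z["a", "b"] <- Z["b", "a"] <- 2
  Z["c", "d"] <- Z["d", "c"] <- 1
  expect_warning(cc <- coupling_correlations(Z), "undefined")
  expect_true(any(is.na(cc$correlations[upper.tri(cc$correlations)])))
  expect_error(coupling_correlations(Z[1:3, 1:3]), "at least 4 states")
})

test_that("null-simulator z-scores are centered near zero", {
  sim <- simulate_null(sim_config(n_progenitors = c(RGC_1 = 50, RGC_2 = 50),
                                  n_genes = 10, n_marker_genes_per_type = 1,
                                  seed = 19))
  cl <- truth_clone_table(sim)
  res <- coupling_zscores(cl, n_perm = 2000, seed = 19)
  off <- res$Z[upper.tri(res$Z)]
  off <- off[!res$mask[upper.tri(res$mask)]]
  expect_lt(abs(mean(off)), 0.5)  # loose unit-scale check; calibrated run in acceptance
})

test_that("coupling result serializes to labeled CSV matrices", {
  dir <- withr::local_tempdir()
  res <- coupling_zscores(toy_clones(), n_perm = 200, seed = 2)
  write_coupling(res, dir)
  z <- as.matrix(read.csv(file.path(dir, "zscores.csv"), row.names = 1))
  expect_equal(unname(z), unname(res$Z), tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(dir, "coupling_summary.json"))
  expect_equal(js$n_perm, 200)
})
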