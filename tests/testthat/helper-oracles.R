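# Independent brute-force oracles used across tests. These deliberately
# recompute everything from first principles (no shared code with the
# package implementations beyond the same documented tie rules).

# Jaccard distance between two 0/1 rows
oracle_jaccard_dist <- function(x, y) {
  inter <- sum(x & y)
  un <- sum(x | y)
  1 - inter / un
}

# Exhaustive-recomputation average-linkage clustering: at every step the
# distance between two clusters is recomputed as the mean over ALL cross
# pairs of original cell-cell Jaccard distances; the minimum pair (ties
# within 1e-9 broken toward clusters holding the lexicographically smallest
# cell) is merged while the minimum is <= cut + 1e-9. Returns an integer
# partition vector aligned with (lexicographically sorted) row names.
oracle_average_linkage <- function(mat, cut = 0.5, tol = 1e-9) {
  mat <- as.matrix(mat)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n <- nrow(mat)
  d0 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d0[i, j] <- oracle_jaccard_dist(mat[i, ] == 1, mat[j, ] == 1)
    }
  }
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d0[clusters[[a]], clusters[[b]]])
        if (dd < bestd - tol) {
          bestd <- dd; best <- list(c(a, b))
        } else if (dd <= bestd + tol) {
          best <- c(best, list(c(a, b)))
        }
      }
    }
    if (bestd > cut + tol) break
    # tie rule: smallest (min member, max member) of the candidate pairs
    key <- vapply(best, function(p) {
      m1 <- min(clusters[[p[1]]], clusters[[p[2]]])
      m2 <- max(min(clusters[[p[1]]]), min(clusters[[p[2]]]))
      m1 * (n + 1) + m2
    }, numeric(1))
    p <- best[[which.min(key)]]
    clusters[[p[1]]] <- c(clusters[[p[1]]], clusters[[p[2]]])
    clusters[[p[2]]] <- NULL
  }
  part <- integer(n)
  for (g in seq_along(clusters)) part[clusters[[g]]] <- g
  # relabel densely by smallest member
  firsts <- vapply(split(seq_len(n), part), min, integer(1))
  rank(firsts)[as.character(part)]
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in tests
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# brute-force shared-clone count by per-clone scan
oracle_shared_count <- function(clones, a, b, min_cells = 2,
                                state_col = "subtype") {
  n <- 0L
  for (cid in unique(clones$clone_id)) {
    st <- clones[[state_col]][clones$clone_id == cid]
    if (a == b) {
      if (sum(st == a) >= min_cells) n <- n + 1L
    } else if (sum(st == a) >= min_cells && sum(st == b) >= min_cells) {
      n <- n + 1L
    }
  }
  n
}

# partitions agree up to label renaming
same_partition <- function(p, q) {
  length(p) == length(q) &&
    all(tapply(q, p, function(v) length(unique(v))) == 1) &&
    all(tapply(p, q, function(v) length(unique(v))) == 1)
}

# random binary cell x barcode matrix with no empty rows/columns
random_incidence <- function(n_cells, n_bc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_cells * n_bc, 1, p), n_cells, n_bc,
                dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                                sprintf("b%02d", seq_len(n_bc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# dense 0/1 matrix -> long pair table
incidence_to_pairs <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  data.frame(cell_bc = rownames(m)[idx[, 1]],
             lineage_bc = colnames(m)[idx[, 2]],
             stringsAsFactors = FALSE)
}

# small simulation config for fast tests
small_config <- function(n1 = 30, n2 = 30, seed = 1, ...) {
  sim_config(n_progenitors = c(RGC_1 = n1, RGC_2 = n2), seed = seed, ...)
}

# two-"timepoint" expression generator: groups drawn i.i.d. from one NB
# distribution, optional Poisson mean shift on the first 10 genes of the
# later group
iid_expr <- function(n_per_group, n_genes = 60, seed = 1, shift = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  mu <- rlnorm(n_genes, log(2), 0.5)
  counts <- matrix(rnbinom(n_genes * n, size = 4, mu = rep(mu, n)), n_genes, n)
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- paste0("c", seq_len(n))
  grp <- rep(c("t0", "t1"), each = n_per_group)
  counts[1:10, grp == "t1"] <- counts[1:10, grp == "t1"] +
    matrix(rpois(10 * n_per_group, shift), 10)
  ann <- data.frame(cell_id = colnames(counts), subtype = "S", timepoint = grp,
                    stringsAsFactors = FALSE)
  list(expr = lognormalize(counts), ann = ann)
}

# clone table from simulator ground truth (bypasses clone calling)
truth_clone_table <- function(sim) {
  merge(sim$truth$cells[, c("cell_id", "clone_id")], sim$annotations,
        by = "cell_id")
}
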