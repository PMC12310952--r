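# Lineage-coupling statistics: observed shared-clone counts between cell
# states, permutation-null moments, z-scores, and the correlation structure
# of the z-score matrix.

# per-clone state-count matrix (clones x states) from integer index vectors
state_count_matrix <- function(clone_idx, state_idx, n_clones, n_states) {
  matrix(tabulate(clone_idx + n_clones * (state_idx - 1L), n_clones * n_states),
         n_clones, n_states)
}

# symmetric shared-clone count matrix: entry (a,b) = number of clones with
# >= min_cells cells of state a AND >= min_cells of state b; the diagonal
# counts clones with >= min_cells of that single state (self-coupling)
shared_count_matrix <- function(clone_idx, state_idx, n_clones, n_states,
                                min_cells) {
  cnt <- state_count_matrix(clone_idx, state_idx, n_clones, n_states)
  p <- cnt >= min_cells
  crossprod(p)
}

prep_states <- function(clones, state_col) {
  if (!all(c("cell_id", "clone_id") %in% names(clones))) {
    stop2("clone table needs cell_id and clone_id columns")
  }
  if (!state_col %in% names(clones)) {
    stop2(sprintf("state column '%s' not found in clone table", state_col))
  }
  # canonical cell order: results independent of input row order
  clones <- clones[order(clones$cell_id), , drop = FALSE]
  lab <- as.character(clones[[state_col]])
  states <- sort(unique(lab))
  list(states = states,
       state_idx = match(lab, states),
       clone_idx = match(clones$clone_id, sort(unique(clones$clone_id))))
}

#' Count clones shared between two cell states
#'
#' A clone is "shared" between two states when it contains at least
#' `min_cells` cells assigned to each state (default 2). With
#' `state_a == state_b` this counts clones with at least `min_cells` cells
#' of that one state — the self-coupling (expansion) diagonal.
#'
#' @param clones Clone table with `cell_id`, `clone_id` and the state
#'   column.
#' @param state_a,state_b State labels.
#' @param min_cells Minimum cells per state within a clone (default 2).
#' @param state_col Column of `clones` holding the state labels (default
#'   `"subtype"`).
#' @return Integer count.
#' @export
shared_clone_count <- function(clones, state_a, state_b, min_cells = 2,
                               state_col = "subtype") {
  min_cells <- check_count(min_cells, "min_cells")
  if (!nrow(clones)) return(0L)
  pr <- prep_states(clones, state_col)
  unknown <- setdiff(c(state_a, state_b), pr$states)
  if (length(unknown)) {
    stop2(sprintf("unknown state(s) %s; known states: %s",
                  paste(unknown, collapse = ", "),
                  paste(pr$states, collapse = ", ")))
  }
  O <- shared_count_matrix(pr$clone_idx, pr$state_idx,
                           max(pr$clone_idx), length(pr$states), min_cells)
  as.integer(O[match(state_a, pr$states), match(state_b, pr$states)])
}

#' Permutation-null lineage-coupling z-scores
#'
#' For every pair of cell states, the observed shared-clone count is
#' compared with its null distribution obtained by shuffling the cell-state
#' labels uniformly over all cells (clone membership fixed, marginal label
#' counts preserved). The z-score is `(O - mu) / sigma` with `mu`, `sigma`
#' the permutation moments (population standard deviation over the
#' `n_perm` permutations). Positive z-scores mean two states co-occur in
#' clones more often than chance (lineage-coupled); negative, less often
#' (anti-coupled). The z-row correlation matrix and an average-linkage
#' ordering of states are attached for heatmap display.
#'
#' Cells of the permutation-degenerate kind (`sigma = 0`) get `Z = 0` and
#' are flagged in `$mask`.
#'
#' @inheritParams shared_clone_count
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation RNG; recorded in the result.
#' @return Object of class `coupling_result`: list with `states`,
#'   `observed`, `mu`, `sigma`, `Z`, `mask`, `correlations`, `order`,
#'   `n_perm`, `min_cells`, `seed`, `n_clones`, `n_cells`, `mc_se`
#'   (Monte-Carlo standard error of each `mu`).
#' @export
coupling_zscores <- function(clones, state_col = "subtype", n_perm = 10000,
                             min_cells = 2, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  min_cells <- check_count(min_cells, "min_cells")
  if (!nrow(clones)) stop2("clone table is empty")
  if (is.factor(clones[[state_col]])) {
    present <- levels(droplevels(clones[[state_col]]))
    empty <- setdiff(levels(clones[[state_col]]), present)
    if (length(empty)) {
      warning("dropping states with zero cells: ",
              paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  pr <- prep_states(clones, state_col)
  S <- length(pr$states)
  if (S < 2) stop2("need at least 2 states with cells")
  K <- max(pr$clone_idx)
  N <- length(pr$clone_idx)

  O <- shared_count_matrix(pr$clone_idx, pr$state_idx, K, S, min_cells)
  sum1 <- matrix(0, S, S); sum2 <- matrix(0, S, S)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- pr$state_idx[sample.int(N)]
      Ob <- shared_count_matrix(pr$clone_idx, perm, K, S, min_cells)
      sum1 <- sum1 + Ob
      sum2 <- sum2 + Ob * Ob
    }
  })
  mu <- sum1 / n_perm
  sigma <- sqrt(pmax(sum2 / n_perm - mu^2, 0))
  mask <- sigma <= 0
  Z <- (O - mu) / ifelse(mask, 1, sigma)
  Z[mask] <- 0
  dimnames(O) <- dimnames(mu) <- dimnames(sigma) <- dimnames(Z) <-
    dimnames(mask) <- list(pr$states, pr$states)

  res <- structure(list(
    states = pr$states, observed = O, mu = mu, sigma = sigma, Z = Z,
    mask = mask, n_perm = n_perm, min_cells = min_cells, seed = seed,
    n_clones = K, n_cells = N, mc_se = sigma / sqrt(n_perm)),
    class = "coupling_result")
  if (S >= 4) {
    cc <- coupling_correlations(res)
    res$correlations <- cc$correlations
    res$order <- cc$order
  } else {
    # off-diagonal-excluded row vectors need >= 2 shared entries
    res$correlations <- NULL
    res$order <- hclust(dist(Z), method = "average")$order
  }
  res
}

#' Correlation structure of the coupling z-score matrix
#'
#' Pearson correlation between the z-score rows of every pair of states,
#' excluding the self-coupling diagonal entries of the two states involved
#' (which would trivially inflate similarity), plus an average-linkage
#' ordering of states by Euclidean distance between z-rows for clustered
#' heatmap display. States whose z-row is constant over the retained
#' entries have undefined correlations; these are set to `NA` with a
#' warning.
#'
#' @param result A `coupling_result` from [coupling_zscores()], or a bare
#'   symmetric z-score matrix with state dimnames.
#' @return List with `correlations` (symmetric matrix, unit diagonal) and
#'   `order` (integer state ordering).
#' @export
coupling_correlations <- function(result) {
  Z <- if (inherits(result, "coupling_result")) result$Z else as.matrix(result)
  S <- nrow(Z)
  if (S < 4) stop2("need at least 4 states for off-diagonal-excluded correlations")
  C <- diag(1, S)
  dimnames(C) <- dimnames(Z)
  warned <- FALSE
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      idx <- setdiff(seq_len(S), c(i, j))
      zi <- Z[i, idx]; zj <- Z[j, idx]
      if (isTRUE(sd(zi) == 0) || isTRUE(sd(zj) == 0)) {
        C[i, j] <- C[j, i] <- NA_real_
        warned <- TRUE
      } else {
        C[i, j] <- C[j, i] <- cor(zi, zj)
      }
    }
  }
  if (warned) {
    warning("constant z-score rows: some correlations are undefined (NA)",
            call. = FALSE)
  }
  ord <- if (S > 2) hclust(dist(Z), method = "average")$order else seq_len(S)
  list(correlations = C, order = ord)
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result: %d states, %d clones, %d cells, %d permutations (seed %d)>\n",
              length(x$states), x$n_clones, x$n_cells, x$n_perm, x$seed))
  cat("z-scores:\n")
  print(round(x$Z, 2))
  invisible(x)
}

#' Write a coupling result to CSV matrices
#'
#' Emits `observed`, `mu`, `sigma`, `zscores`, `correlations` and `mask`
#' as labeled CSV matrices plus a JSON summary of the run parameters.
#'
#' @param result A `coupling_result`.
#' @param dir Output directory.
#' @return Invisibly, the vector of written paths.
#' @export
write_coupling <- function(result, dir) {
  stopifnot(inherits(result, "coupling_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- list(observed = result$observed, mu = result$mu,
               sigma = result$sigma, zscores = result$Z,
               mask = result$mask * 1)
  if (!is.null(result$correlations)) mats$correlations <- result$correlations
  paths <- character(0)
  for (nm in names(mats)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(mats[[nm]]), p)
    paths <- c(paths, p)
  }
  sm <- file.path(dir, "coupling_summary.json")
  jsonlite::write_json(list(
    states = result$states, state_order = result$order,
    n_perm = result$n_perm, min_cells = result$min_cells,
    seed = result$seed, n_clones = result$n_clones,
    n_cells = result$n_cells), sm, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, sm))
}
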