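# Expression-side statistics: depth log-normalization, the
# scrambled-normalized PCA-distance stability statistic, and binned-control
# gene-set module scores.

#' Log-normalize a count matrix
#'
#' Standard depth normalization for droplet data: each count is scaled by
#' its cell's total transcript count, multiplied by `scale_factor`
#' (default 10,000), and transformed with the natural log1p:
#' `x' = ln(1 + scale_factor * x / colsum)`. Zeros map to zeros, so
#' sparsity is preserved, and every cell satisfies the conservation
#' identity `sum(exp(x') - 1) = scale_factor`.
#'
#' @param raw Genes x cells count matrix (dense or sparse), layer `"raw"`.
#' @param scale_factor Depth scale (default 1e4).
#' @return Matrix of the same shape and sparsity, layer attribute
#'   `"lognorm"`.
#' @examples
#' m <- matrix(c(1, 9999, 5, 5), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' lognormalize(m)["g1", "c1"] # ln(2)
#' @export
lognormalize <- function(raw, scale_factor = 10000) {
  layer <- attr(raw, "layer")
  if (!is.null(layer) && layer != "raw") {
    stop2("input layer is '", layer, "', expected raw counts")
  }
  totals <- Matrix::colSums(raw)
  if (any(totals == 0)) {
    bad <- colnames(raw)[totals == 0]
    stop2("cells with zero total counts: ",
          paste(head(bad), collapse = ", "))
  }
  if (inherits(raw, "sparseMatrix")) {
    out <- raw %*% Matrix::Diagonal(x = scale_factor / totals)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(raw)
  } else {
    out <- log1p(sweep(raw, 2, totals / scale_factor, "/"))
  }
  attr(out, "layer") <- "lognorm"
  attr(out, "scale_factor") <- scale_factor
  out
}

# mean Euclidean distance over all cross pairs between score-row blocks
mean_cross_distance <- function(A, B) {
  ra <- rowSums(A^2); rb <- rowSums(B^2)
  d2 <- outer(ra, rb, "+") - 2 * A %*% t(B)
  mean(sqrt(pmax(d2, 0)))
}

#' Scrambled-normalized PCA distance across timepoints
#'
#' Measures how far a cell subtype moves in transcriptional space between a
#' reference timepoint and each later timepoint, normalized so that 1
#' means "no more than any random split of the data". Principal components
#' are computed once on the whole dataset (per-gene centered, optionally
#' standardized); for each queried timepoint `t`, `D` is the average
#' distance in the first `n_components` PC scores between all (reference
#' cell, time-`t` cell) pairs of the subtype. The normalizer `D_s` is the
#' average cross-group distance over `n_scrambles` random half-splits of
#' the whole dataset, and `R = D / D_s` is reported.
#'
#' @param expr Log-normalized genes x cells matrix (see [lognormalize()]).
#' @param annotations Data frame with `cell_id` plus the subtype and
#'   timepoint columns; must cover the columns of `expr`.
#' @param subtype Subtype whose stability is measured (or a vector).
#' @param ref_time Reference timepoint label.
#' @param times Later timepoint labels to compare against.
#' @param n_components Number of leading PCs (default 30).
#' @param n_scrambles Random half-splits averaged into `D_s` (default 20;
#'   1 gives the single-split reading).
#' @param seed Seed for the scrambled splits.
#' @param mode `"pairwise"` (mean over all cross pairs, default) or
#'   `"centroid"` (distance between group means).
#' @param standardize Scale genes to unit variance before PCA (default
#'   TRUE; zero-variance genes are dropped).
#' @param subtype_col,time_col Annotation column names.
#' @return Data frame with one row per (subtype, timepoint): `subtype`,
#'   `timepoint`, `D`, `D_s`, `R`.
#' @export
pca_distance <- function(expr, annotations, subtype, ref_time, times,
                         n_components = 30, n_scrambles = 20, seed = 1L,
                         mode = c("pairwise", "centroid"),
                         standardize = TRUE,
                         subtype_col = "subtype", time_col = "timepoint") {
  mode <- match.arg(mode)
  n_components <- check_count(n_components, "n_components")
  n_scrambles <- check_count(n_scrambles, "n_scrambles")
  layer <- attr(expr, "layer")
  if (!is.null(layer) && layer != "lognorm") {
    warning("expression layer is '", layer, "', expected lognorm", call. = FALSE)
  }
  ann <- annotations[match(colnames(expr), annotations$cell_id), , drop = FALSE]
  if (any(is.na(ann$cell_id))) stop2("annotations do not cover all cells")

  X <- t(as.matrix(expr))
  v <- apply(X, 2, stats::var)
  X <- X[, v > 0, drop = FALSE]
  if (!ncol(X)) stop2("all cells identical: distances are degenerate (D = D_s = 0)")
  if (n_components > min(dim(X))) {
    stop2(sprintf("n_components = %d exceeds min(cells, informative genes) = %d",
                  n_components, min(dim(X))))
  }
  X <- scale(X, center = TRUE, scale = standardize)
  scores <- prcomp(X, center = FALSE, scale. = FALSE,
                   rank. = n_components)$x

  # scrambled normalizer: random half-splits of the whole dataset
  n <- nrow(scores)
  ds <- with_seed(seed, {
    vapply(seq_len(n_scrambles), function(i) {
      half <- sample.int(n, floor(n / 2))
      mean_group_distance(scores[half, , drop = FALSE],
                          scores[-half, , drop = FALSE], mode)
    }, numeric(1))
  })
  D_s <- mean(ds)
  if (D_s <= 0) stop2("scrambled distance is zero: cells are identical in PC space")

  rows <- lapply(times, function(tt) {
    ia <- which(ann[[subtype_col]] %in% subtype & ann[[time_col]] == ref_time)
    ib <- which(ann[[subtype_col]] %in% subtype & ann[[time_col]] == tt)
    if (length(ia) < 2 || length(ib) < 2) {
      stop2(sprintf("fewer than 2 cells of %s at %s/%s",
                    paste(subtype, collapse = "+"), ref_time, tt))
    }
    D <- mean_group_distance(scores[ia, , drop = FALSE],
                             scores[ib, , drop = FALSE], mode)
    data.frame(subtype = paste(subtype, collapse = "+"), timepoint = tt,
               D = D, D_s = D_s, R = D / D_s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_components") <- n_components
  attr(out, "n_scrambles") <- n_scrambles
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  out
}

mean_group_distance <- function(A, B, mode) {
  if (mode == "centroid") {
    sqrt(sum((colMeans(A) - colMeans(B))^2))
  } else {
    mean_cross_distance(A, B)
  }
}

#' Gene-set module score with expression-binned controls
#'
#' Per-cell enrichment of a gene set relative to matched background: genes
#' are binned by their average expression into `n_bins` equal-frequency
#' bins, each set gene contributes `n_ctrl` control genes sampled (with
#' replacement) from its own bin, and the score is the per-cell mean
#' expression of the set minus the mean over all sampled controls. Scores
#' near zero mean the set behaves like depth-matched background.
#'
#' @param expr Log-normalized genes x cells matrix.
#' @param gene_set Character vector of gene IDs; must all be rows of
#'   `expr`.
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  n_bins <- check_count(n_bins, "n_bins")
  n_ctrl <- check_count(n_ctrl, "n_ctrl")
  gene_set <- unique(gene_set)
  missing_genes <- setdiff(gene_set, rownames(expr))
  if (length(missing_genes) == length(gene_set) || !length(gene_set)) {
    stop2("gene set has no genes present in the expression matrix")
  }
  gene_set <- setdiff(gene_set, missing_genes)
  G <- nrow(expr)
  n_bins <- min(n_bins, G)
  avg <- Matrix::rowMeans(expr)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / G)
  names(bin) <- rownames(expr)
  set_idx <- match(gene_set, rownames(expr))
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(g) {
      pool <- which(bin == bin[g])
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  set_mean <- Matrix::colMeans(expr[set_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(expr[ctrl_idx, , drop = FALSE])
  score <- set_mean - ctrl_mean
  names(score) <- colnames(expr)
  score
}
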