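#' Jaccard similarity between two barcode sets
#'
#' `|a n b| / |a u b|`, the similarity on which clone calling clusters
#' cells: cells of one clone share (most of) their integration-barcode set.
#'
#' @param a,b Non-empty character vectors of barcode IDs (treated as sets).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard_similarity(c("B1", "B2"), c("B2", "B3")) # 1/3
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) {
    stop2("barcode sets must be non-empty (drop barcode-less cells upstream)")
  }
  length(intersect(a, b)) / length(union(a, b))
}

# Pairwise Jaccard distance (1 - similarity) between the rows of a binary
# sparse matrix, returned dense.
jaccard_distance_rows <- function(m) {
  inter <- as.matrix(Matrix::tcrossprod(m))
  sz <- Matrix::rowSums(m)
  un <- outer(sz, sz, "+") - inter
  d <- 1 - inter / un
  diag(d) <- 0
  d
}

# Average-linkage (UPGMA) agglomeration over weighted nodes with a
# deterministic tie rule: among pairs whose distance is within `tol` of the
# current minimum, merge the pair whose clusters contain the
# lexicographically smallest original labels. Weighted nodes make the
# procedure exactly equivalent to running UPGMA on the expanded set of
# original points (cluster-cluster distance is the mean over all original
# cross pairs). Stops early once the minimum exceeds `cut + tol` when `cut`
# is given.
upgma_engine <- function(D, weights, rank0, cut = NULL, tol = 1e-9) {
  u <- nrow(D)
  members <- as.list(seq_len(u))
  w <- as.numeric(weights)
  rnk <- as.numeric(rank0)
  active <- rep(TRUE, u)
  diag(D) <- Inf
  merges <- list()
  while (sum(active) > 1) {
    m <- min(D[active, active, drop = FALSE])
    if (!is.null(cut) && m > cut + tol) break
    cand <- which(D <= m + tol & upper.tri(D), arr.ind = TRUE)
    # tie rule: smallest (min rank, max rank) over the two clusters
    k1 <- pmin(rnk[cand[, 1]], rnk[cand[, 2]])
    k2 <- pmax(rnk[cand[, 1]], rnk[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    merges[[length(merges) + 1L]] <- c(i, j, D[i, j])
    # weighted average update into i
    upd <- (w[i] * D[i, ] + w[j] * D[j, ]) / (w[i] + w[j])
    D[i, ] <- upd; D[, i] <- upd
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer(0)
    w[i] <- w[i] + w[j]
    rnk[i] <- min(rnk[i], rnk[j])
    active[j] <- FALSE
  }
  list(members = members[active], merges = merges, active = active, rank = rnk)
}

#' Assign clones by average-linkage clustering of Jaccard similarities
#'
#' Cells are clustered on Jaccard distance (1 - similarity) between their
#' integration-barcode sets with average linkage; the dendrogram is cut at
#' `cut_height` and each resulting cluster becomes one clone. Identical
#' barcode sets are collapsed into weighted nodes first, which leaves the
#' result exactly unchanged while making the agglomeration fast at
#' experiment scale. The procedure is deterministic: distance ties are
#' broken toward the clusters containing the lexicographically smallest
#' cell IDs, and comparisons use a 1e-9 tolerance so that exact rational
#' ties are recognized under floating-point arithmetic.
#'
#' @param matrix Binary cell-by-barcode matrix from [build_matrix()]; every
#'   row must have at least one nonzero.
#' @param cut_height Dendrogram cut in `(0, 1]` (default 0.5: cells sharing
#'   the majority of their integrations merge, single-barcode collisions
#'   between multi-barcode clones do not).
#' @param annotations Optional per-cell annotation data frame with a
#'   `cell_id` column; its columns are joined onto the result.
#' @return Clone table: data frame with `cell_id`, `clone_id` (dense
#'   integers from 1, ordered by each clone's smallest cell ID) and any
#'   annotation columns.
#' @export
call_clones <- function(matrix, cut_height = 0.5, annotations = NULL) {
  if (!is.numeric(cut_height) || length(cut_height) != 1 ||
      cut_height <= 0 || cut_height > 1) {
    stop2("`cut_height` must lie in (0, 1]")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop2("matrix needs cell row names and barcode column names")
  }
  nz <- Matrix::rowSums(matrix != 0)
  if (any(nz == 0)) {
    stop2("cells without barcodes present: ",
          paste(head(rownames(matrix)[nz == 0]), collapse = ", "))
  }
  ord <- order(rownames(matrix))
  m <- matrix[ord, , drop = FALSE]
  cells <- rownames(m)

  # collapse identical barcode sets into weighted nodes
  mt <- Matrix::t(m)
  key <- vapply(seq_len(ncol(mt)), function(i) {
    paste(mt@i[(mt@p[i] + 1):mt@p[i + 1]], collapse = ",")
  }, character(1))
  first <- !duplicated(key)
  node_of <- match(key, key[first])
  um <- m[first, , drop = FALSE]
  weights <- tabulate(node_of, sum(first))
  rank0 <- match(seq_len(sum(first)), node_of)  # first (smallest) cell per node

  if (nrow(um) == 1) {
    cl <- rep(1L, length(cells))
  } else {
    D <- jaccard_distance_rows(um)
    res <- upgma_engine(D, weights, rank0, cut = cut_height)
    node_cluster <- integer(sum(first))
    for (g in seq_along(res$members)) node_cluster[res$members[[g]]] <- g
    cell_cluster <- node_cluster[node_of]
    # dense clone ids ordered by smallest member cell
    firsts <- tapply(seq_along(cells), cell_cluster, min)
    relabel <- rank(firsts)
    cl <- as.integer(relabel[as.character(cell_cluster)])
  }
  out <- data.frame(cell_id = cells, clone_id = cl, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    if (!"cell_id" %in% names(annotations)) {
      stop2("`annotations` must contain a cell_id column")
    }
    out <- merge(out, annotations, by = "cell_id", all.x = TRUE, sort = TRUE)
  }
  out <- out[order(out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cut_height") <- cut_height
  out
}

#' Full average-linkage dendrogram of cells
#'
#' Runs the same Jaccard/average-linkage agglomeration as [call_clones()]
#' to completion at cell resolution and returns a standard `hclust` object
#' (exportable to Newick via [ape::as.phylo()]), for inspection of the
#' clone structure around the cut height.
#'
#' @inheritParams call_clones
#' @return An object of class `hclust`.
#' @export
clone_dendrogram <- function(matrix) {
  ord <- order(rownames(matrix))
  m <- matrix[ord, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop2("need at least two cells for a dendrogram")
  D <- jaccard_distance_rows(m)
  res <- upgma_engine(D, rep(1, n), seq_len(n), cut = NULL)
  merge <- matrix(0L, length(res$merges), 2)
  height <- numeric(length(res$merges))
  node_ref <- -seq_len(n)  # hclust convention: negative = singleton
  for (k in seq_along(res$merges)) {
    mk <- res$merges[[k]]
    merge[k, ] <- sort(c(node_ref[mk[1]], node_ref[mk[2]]))
    height[k] <- mk[3]
    node_ref[mk[1]] <- k
  }
  hc <- structure(list(
    merge = merge, height = height,
    order = hclust_order(merge, n),
    labels = rownames(m), method = "average",
    dist.method = "jaccard", call = match.call()), class = "hclust")
  hc
}

# leaf order by traversing the merge tree
hclust_order <- function(merge, n) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  if (nrow(merge) == 0) return(seq_len(n))
  got <- leaves(nrow(merge))
  c(got, setdiff(seq_len(n), got))
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object, e.g. from [clone_dendrogram()].
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Clone-size summary
#'
#' @param clones Clone table from [call_clones()] (needs `clone_id`).
#' @return List with `n_clones`, `n_cells`, `mean_size`, and `size_hist`
#'   (a table over integer clone sizes).
#' @examples
#' tb <- data.frame(cell_id = letters[1:9],
#'                  clone_id = c(1, 1, 2, 2, 3, 3, 3, 3, 3))
#' clone_size_stats(tb)$mean_size # 3
#' @export
clone_size_stats <- function(clones) {
  if (!nrow(clones)) stop2("clone table is empty")
  sizes <- as.integer(table(clones$clone_id))
  list(n_clones = length(sizes),
       n_cells = nrow(clones),
       mean_size = mean(sizes),
       size_hist = table(factor(sizes, levels = seq_len(max(sizes)))))
}
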