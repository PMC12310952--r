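#' Extract lineage barcodes from FASTQ reads
#'
#' Reads carry the lineage barcode between two constant flanking adapters;
#' the droplet cell barcode and UMI are encoded in the read name as
#' `cell<sep>umi` (the convention used when cell/UMI are folded into read
#' names during preprocessing). The insert between the flanks is kept when
#' it is at least `min_len` bases long and the cell barcode is on the
#' whitelist; surviving observations are aggregated into
#' cell-UMI-barcode triples with `reads` = number of supporting reads.
#'
#' Flank matching is exact substring search by default; `max_mismatch`
#' allows a Hamming tolerance. Reads lacking either flank, with short
#' inserts, or off-whitelist cells are counted in the attached report and
#' skipped, never fatal.
#'
#' @param fastq Path to a FASTQ file (gzip transparent).
#' @param flank5,flank3 Non-empty adapter sequences bounding the barcode.
#' @param min_len Minimum barcode length in bases; shorter inserts are
#'   excluded (default 37).
#' @param whitelist Character vector of admissible cell barcodes, normally
#'   the cell IDs of the expression dataset.
#' @param id_sep Separator between cell barcode and UMI in the read name.
#' @param max_mismatch Hamming mismatches tolerated in each flank (default 0).
#' @return Data frame of triples (`cell_bc`, `umi`, `lineage_bc`, `reads`)
#'   with a `report` attribute of per-stage counts.
#' @export
extract_barcodes <- function(fastq, flank5, flank3, min_len = 37,
                             whitelist, id_sep = ":", max_mismatch = 0) {
  if (!nzchar(flank5) || !nzchar(flank3)) stop2("flank sequences must be non-empty")
  min_len <- check_count(min_len, "min_len", min = 1)
  if (missing(whitelist) || !length(whitelist)) {
    stop2("a cell-barcode `whitelist` is required")
  }
  rec <- read_fastq_records(fastq)
  ids <- sub("\\s.*$", "", rec$name)
  parts <- strsplit(ids, id_sep, fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) {
    stop2(sprintf("FASTQ record %d: read name %s does not encode cell%sumi",
                  which(bad)[1], ids[which(bad)[1]], id_sep))
  }
  cell <- vapply(parts, `[[`, character(1), 1)
  umi <- vapply(parts, `[[`, character(1), 2)

  ins <- find_insert(rec$seq, flank5, flank3, max_mismatch)
  no_flank <- is.na(ins)
  short <- !no_flank & nchar(ins) < min_len
  off_wl <- !no_flank & !short & !(cell %in% whitelist)
  keep <- !no_flank & !short & !off_wl

  if (any(keep)) {
    key <- paste(cell[keep], umi[keep], ins[keep], sep = "\r")
    cnt <- table(key)
    sp <- strsplit(names(cnt), "\r", fixed = TRUE)
    triples <- data.frame(
      cell_bc = vapply(sp, `[[`, character(1), 1),
      umi = vapply(sp, `[[`, character(1), 2),
      lineage_bc = vapply(sp, `[[`, character(1), 3),
      reads = as.integer(cnt),
      stringsAsFactors = FALSE)
    triples <- triples[order(triples$cell_bc, triples$lineage_bc, triples$umi), ,
                       drop = FALSE]
    rownames(triples) <- NULL
  } else {
    triples <- empty_triples()
  }
  attr(triples, "report") <- list(
    n_reads = length(rec$seq), n_no_flank = sum(no_flank),
    n_short_insert = sum(short), n_off_whitelist = sum(off_wl),
    n_reads_kept = sum(keep), n_triples = nrow(triples),
    min_len = min_len, max_mismatch = max_mismatch)
  triples
}

empty_triples <- function() {
  data.frame(cell_bc = character(0), umi = character(0),
             lineage_bc = character(0), reads = integer(0),
             stringsAsFactors = FALSE)
}

# Minimal 4-line FASTQ reader (gzip transparent). Returns names (without
# leading @) and sequences; malformed records raise an error naming the
# record index.
read_fastq_records <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4 != 0) {
    stop2(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (record %d truncated)",
                  length(lines), length(lines) %/% 4 + 1))
  }
  n <- length(lines) %/% 4
  name <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(name, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop2(sprintf("malformed FASTQ record %d near line %d", bad[1], (bad[1] - 1) * 4 + 1))
  }
  list(name = sub("^@", "", name), seq = seqs)
}

# Insert between the first occurrence of flank5 and the first occurrence of
# flank3 after it; NA when either flank is absent. Hamming-tolerant search
# when max_mismatch > 0.
find_insert <- function(seqs, flank5, flank3, max_mismatch = 0) {
  if (max_mismatch == 0) {
    p5 <- regexpr(flank5, seqs, fixed = TRUE)
    start <- ifelse(p5 > 0, p5 + nchar(flank5), NA_integer_)
    rest <- ifelse(is.na(start), NA_character_, substring(seqs, start))
    p3 <- ifelse(is.na(rest), -1L, regexpr(flank3, rest, fixed = TRUE))
    ifelse(is.na(start) | p3 < 1, NA_character_,
           substring(rest, 1, p3 - 1))
  } else {
    vapply(seqs, function(s) {
      p5 <- hamming_find(s, flank5, max_mismatch, from = 1L)
      if (is.na(p5)) return(NA_character_)
      p3 <- hamming_find(s, flank3, max_mismatch, from = p5 + nchar(flank5))
      if (is.na(p3)) return(NA_character_)
      substr(s, p5 + nchar(flank5), p3 - 1)
    }, character(1), USE.NAMES = FALSE)
  }
}

# first position >= from where `pat` matches `s` with <= k mismatches
hamming_find <- function(s, pat, k, from = 1L) {
  n <- nchar(s); m <- nchar(pat)
  if (n - from + 1 < m) return(NA_integer_)
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  for (i in from:(n - m + 1)) {
    if (sum(sc[i:(i + m - 1)] != pc) <= k) return(i)
  }
  NA_integer_
}

#' Filter cell-UMI-barcode triples by read and UMI support
#'
#' Two-stage molecular filter: triples supported by fewer than `min_reads`
#' reads are removed, then cell-barcode pairs with fewer than `min_umis`
#' distinct surviving UMIs are removed. The defaults (10 reads, 6 UMIs) are
#' the standard thresholds for transposon lineage-barcode libraries.
#'
#' @param triples Aggregated triples data frame (`cell_bc`, `umi`,
#'   `lineage_bc`, `reads`); must be unique on (cell, UMI, barcode).
#' @param min_reads Minimum reads per triple (default 10).
#' @param min_umis Minimum distinct UMIs per cell-barcode pair (default 6).
#' @return Data frame of surviving pairs (`cell_bc`, `lineage_bc`,
#'   `umi_count`) with a `report` attribute of per-stage in/out counts.
#'   Empty input yields an empty table plus report.
#' @export
filter_triples <- function(triples, min_reads = 10, min_umis = 6) {
  min_reads <- check_count(min_reads, "min_reads", min = 1)
  min_umis <- check_count(min_umis, "min_umis", min = 1)
  check_triples(triples)
  key <- paste(triples$cell_bc, triples$umi, triples$lineage_bc, sep = "\r")
  if (anyDuplicated(key)) {
    stop2("triples are not aggregated: duplicate (cell, UMI, barcode) rows present")
  }
  pass <- triples$reads >= min_reads
  surv <- triples[pass, , drop = FALSE]
  if (nrow(surv)) {
    pk <- paste(surv$cell_bc, surv$lineage_bc, sep = "\r")
    cnt <- table(pk)
    keep <- cnt[cnt >= min_umis]
    sp <- strsplit(names(keep), "\r", fixed = TRUE)
    pairs <- data.frame(
      cell_bc = vapply(sp, `[[`, character(1), 1),
      lineage_bc = vapply(sp, `[[`, character(1), 2),
      umi_count = as.integer(keep),
      stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$cell_bc, pairs$lineage_bc), , drop = FALSE]
    rownames(pairs) <- NULL
    n_pairs_in <- length(cnt)
  } else {
    pairs <- data.frame(cell_bc = character(0), lineage_bc = character(0),
                        umi_count = integer(0), stringsAsFactors = FALSE)
    n_pairs_in <- 0L
  }
  attr(pairs, "report") <- list(
    n_triples_in = nrow(triples),
    n_triples_pass_reads = sum(pass),
    n_pairs_in = n_pairs_in,
    n_pairs_out = nrow(pairs),
    min_reads = min_reads, min_umis = min_umis)
  pairs
}

check_triples <- function(triples) {
  need <- c("cell_bc", "umi", "lineage_bc", "reads")
  if (!is.data.frame(triples) || !all(need %in% names(triples))) {
    stop2("triples must be a data frame with columns ",
          paste(need, collapse = ", "))
  }
  if (nrow(triples)) {
    if (any(!nzchar(triples$cell_bc)) || any(!nzchar(triples$umi)) ||
        any(!nzchar(triples$lineage_bc))) {
      stop2("triples contain empty cell/UMI/barcode fields")
    }
    if (any(triples$reads < 1)) stop2("triple read counts must be >= 1")
  }
  invisible(TRUE)
}

#' Build the binary cell-by-barcode incidence matrix
#'
#' Rows are cells, columns lineage barcodes, both in lexicographic order;
#' only cells with at least one surviving pair appear. When the full cell
#' universe is supplied via `all_cells`, barcode-less cells are counted in
#' the drop report.
#'
#' @param pairs Filtered pair table from [filter_triples()] (`cell_bc`,
#'   `lineage_bc`, ...); duplicate pairs are rejected.
#' @param all_cells Optional character vector of all candidate cells (e.g.
#'   the whitelist) used to report cells dropped for lack of barcodes.
#' @return Sparse binary `dgCMatrix` (cells x barcodes) with a `report`
#'   attribute.
#' @export
build_matrix <- function(pairs, all_cells = NULL) {
  if (!is.data.frame(pairs) || !all(c("cell_bc", "lineage_bc") %in% names(pairs))) {
    stop2("pairs must be a data frame with columns cell_bc, lineage_bc")
  }
  key <- paste(pairs$cell_bc, pairs$lineage_bc, sep = "\r")
  if (anyDuplicated(key)) stop2("duplicate (cell, barcode) pair rows")
  cells <- sort(unique(pairs$cell_bc))
  bcs <- sort(unique(pairs$lineage_bc))
  m <- Matrix::sparseMatrix(
    i = match(pairs$cell_bc, cells),
    j = match(pairs$lineage_bc, bcs),
    x = 1,
    dims = c(length(cells), length(bcs)),
    dimnames = list(cells, bcs))
  dropped <- if (is.null(all_cells)) character(0) else setdiff(all_cells, cells)
  attr(m, "report") <- list(
    n_cells = length(cells), n_barcodes = length(bcs),
    n_pairs = nrow(pairs), n_dropped_cells = length(dropped),
    dropped_cells = dropped)
  m
}

#' Read and write triple tables
#'
#' Tab-separated with mandatory header `cell_bc umi lineage_bc reads`.
#'
#' @param triples Triples data frame.
#' @param path File path.
#' @return `read_triples` returns the triples data frame; `write_triples`
#'   returns `path` invisibly.
#' @export
write_triples <- function(triples, path) {
  check_triples(triples)
  write.table(triples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triples
#' @export
read_triples <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(cell_bc = "character", umi = "character",
                                  lineage_bc = "character", reads = "integer"))
  need <- c("cell_bc", "umi", "lineage_bc", "reads")
  if (!all(need %in% names(tr))) {
    stop2("triple file must have header columns ", paste(need, collapse = ", "))
  }
  check_triples(tr[need])
  tr[need]
}

#' Read and write the cell-by-barcode matrix
#'
#' Two interchange formats: long CSV (`cell`, `barcode`, `value`) and
#' MatrixMarket (`.mtx` with `<path>.rownames` / `<path>.colnames`
#' sidecars). Reading reconstructs the identical sparse binary matrix.
#'
#' @param m Sparse cell-by-barcode matrix.
#' @param path Output path; format chosen by extension (`.csv` or `.mtx`).
#' @return `read_matrix` returns the matrix; `write_matrix` returns `path`
#'   invisibly.
#' @export
write_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(m, path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  } else {
    idx <- Matrix::which(m != 0, arr.ind = TRUE)
    df <- data.frame(cell = rownames(m)[idx[, 1]],
                     barcode = colnames(m)[idx[, 2]],
                     value = 1L, stringsAsFactors = FALSE)
    df <- df[order(df$cell, df$barcode), , drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix") * 1
    dimnames(m) <- list(readLines(paste0(path, ".rownames")),
                        readLines(paste0(path, ".colnames")))
    m
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    build_matrix(data.frame(cell_bc = df$cell, lineage_bc = df$barcode,
                            stringsAsFactors = FALSE))
  }
}
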