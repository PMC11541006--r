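#' Read a windowed single-cell count matrix from MatrixMarket + BED + TSV
#'
#' Loads the standard on-disk triple: a sparse MatrixMarket counts file
#' (cells x windows), a BED file of windows (optionally with a 4th `gc`
#' column and 5th `blacklisted` flag), and a barcode list (one per line).
#'
#' @param mtx Path to the MatrixMarket counts (cells x windows).
#' @param windows_bed Path to the window BED (`chrom`, `start`, `end`
#'   [, `gc`, `blacklisted`]).
#' @param barcodes Optional path to a one-column barcode file.
#' @return A list with `counts` (sparse Matrix, barcodes as rownames) and
#'   `windows` (tibble).
#' @export
read_window_counts <- function(mtx, windows_bed, barcodes = NULL) {
  counts <- Matrix::readMM(mtx)
  cols <- c("chrom", "start", "end", "gc", "blacklisted")
  bed <- utils::read.table(windows_bed, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- cols[seq_len(ncol(bed))]
  bed <- tibble::as_tibble(bed)
  if (!"blacklisted" %in% names(bed)) bed$blacklisted <- FALSE
  if (nrow(bed) != ncol(counts)) {
    stop("window BED rows must match count matrix columns", call. = FALSE)
  }
  if (!is.null(barcodes)) {
    bc <- readLines(barcodes)
    if (length(bc) != nrow(counts)) {
      stop("barcode count must match count matrix rows", call. = FALSE)
    }
    rownames(counts) <- bc
  }
  list(counts = counts, windows = bed)
}

#' Read a daughter-pair signal table
#'
#' Tab-separated with header: `pair_id`, `species`, `signal_d1`,
#' `signal_d2`, and optionally `fusion_fraction`, `condition`.
#'
#' @param path File path.
#' @return A tibble in the long format accepted by [pair_proportions()].
#' @export
read_pairs_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Write simulation leaves as TSV
#'
#' @param sim An `ecdna_sim` object.
#' @param path Output path (columns `cell_id`, `k1`, `k2`).
#' @return `path`, invisibly.
#' @export
write_leaves_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "ecdna_sim"))
  df <- data.frame(cell_id = sim$leaves$cell, k1 = sim$leaves$k1,
                   k2 = sim$leaves$k2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
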