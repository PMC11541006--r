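#' Background-normalised single-cell copy number from windowed counts
#'
#' Estimates per-cell copy number for each genomic window from insertion
#' counts by comparing each window's insertions-per-bp to the mean rate of
#' its `n_neighbours` nearest windows in GC content. For window `w` in cell
#' `c`: `FC = rate(c, w) / mean(rate(c, neighbours(w)))` and
#' `CN = 2 * 2^(log2 FC) = 2 * FC`, i.e. a window indistinguishable from its
#' GC-matched background is diploid.
#'
#' Neighbours are ranked by `|gc - gc_w|` among non-blacklisted windows,
#' excluding the window itself and any window overlapping it (sliding windows
#' share sequence); ties are broken by genomic distance (windows on other
#' chromosomes rank last). When a cell has a zero neighbour-mean rate for
#' some window, one pseudo-insertion per window is added to that cell's
#' counts before rates are formed and the cell is flagged.
#'
#' @param counts A cells x windows matrix of non-negative integer insertion
#'   counts (dense or `Matrix` sparse); rownames are cell barcodes.
#' @param windows A data frame describing the columns of `counts`, with
#'   `chrom`, `start`, `end` (0-based half-open) and `gc` in `[0, 1]`;
#'   optional logical `blacklisted`.
#' @param n_neighbours Number of GC-matched background windows (default 100).
#' @return An object of class `cn_matrix`: list with `cn` (dense cells x
#'   windows matrix over the retained, non-blacklisted windows), `windows`
#'   (the retained window table), `pseudocount_cells` (logical per cell),
#'   and `n_neighbours`.
#' @examples
#' syn <- gen_counts_matrix(n_cells = 20, n_tiles = 150, depth = 2000,
#'                          seed = 1)
#' cn <- compute_copy_number(syn$counts, syn$windows)
#' cn$cn[1:3, 1:3]
#' @export
compute_copy_number <- function(counts, windows, n_neighbours = 100) {
  windows <- tibble::as_tibble(windows)
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(windows)),
            ncol(counts) == nrow(windows))
  if (any(windows$end <= windows$start)) {
    stop("windows must satisfy end > start", call. = FALSE)
  }
  if (!"blacklisted" %in% names(windows)) windows$blacklisted <- FALSE
  keep <- !windows$blacklisted
  counts <- as.matrix(counts)[, keep, drop = FALSE]
  windows <- windows[keep, ]
  w <- nrow(windows)
  if (w < n_neighbours + 1) {
    stop("need more than `n_neighbours` non-blacklisted windows (have ",
         w, ")", call. = FALSE)
  }
  nbr <- gc_neighbours(windows, n_neighbours)
  width <- windows$end - windows$start
  # neighbour-averaging operator: A[j, w] = 1/n for j in neighbours(w)
  A <- Matrix::sparseMatrix(
    i = as.vector(nbr), j = rep(seq_len(w), each = n_neighbours),
    x = 1 / n_neighbours, dims = c(w, w))
  rate <- sweep(counts, 2, width, "/")
  bg <- as.matrix(rate %*% A)
  flagged <- apply(bg, 1, function(x) any(x <= 0))
  if (any(flagged)) {
    rate_pc <- sweep(counts[flagged, , drop = FALSE] + 1, 2, width, "/")
    bg[flagged, ] <- as.matrix(rate_pc %*% A)
    rate[flagged, ] <- rate_pc
  }
  cn <- 2 * rate / bg
  dimnames(cn) <- list(rownames(counts), window_id(windows))
  structure(
    list(cn = cn, windows = windows,
         pseudocount_cells = flagged, n_neighbours = n_neighbours),
    class = "cn_matrix")
}

window_id <- function(windows) {
  paste0(windows$chrom, ":", windows$start, "-", windows$end)
}

# For each window, the indices of its n GC-nearest non-overlapping windows.
gc_neighbours <- function(windows, n) {
  w <- nrow(windows)
  chrom <- windows$chrom
  start <- windows$start
  end <- windows$end
  gc <- windows$gc
  mid <- (start + end) / 2
  out <- matrix(0L, nrow = n, ncol = w)
  big <- 1e15
  for (j in seq_len(w)) {
    dgc <- abs(gc - gc[j])
    same <- chrom == chrom[j]
    overlap <- same & start < end[j] & end > start[j]
    dgc[j] <- Inf
    dgc[overlap] <- Inf
    gdist <- ifelse(same, abs(mid - mid[j]), big)
    ord <- order(dgc, gdist)
    out[, j] <- ord[seq_len(n)]
  }
  out
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat("<cn_matrix> ", nrow(x$cn), " cells x ", ncol(x$cn), " windows, ",
      sum(x$pseudocount_cells), " low-coverage cell(s) used a pseudocount\n",
      sep = "")
  invisible(x)
}

#' @method tidy cn_matrix
#' @export
tidy.cn_matrix <- function(x, ...) {
  tibble::as_tibble(x$cn, rownames = "cell") %>%
    tidyr::pivot_longer(-"cell", names_to = "window", values_to = "cn")
}

#' Per-cell gene copy number
#'
#' Averages the copy number of all windows overlapping each gene interval
#' (any shared base, half-open arithmetic). Genes with no overlapping
#' retained window get `NA` with a warning.
#'
#' @param cn A `cn_matrix` from [compute_copy_number()].
#' @param genes A data frame with `gene`, `chrom`, `start`, `end`.
#' @return A tibble: `cell`, one column per gene with its mean copy number.
#' @export
gene_copy_number <- function(cn, genes) {
  stopifnot(inherits(cn, "cn_matrix"),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  wins <- cn$windows
  cells <- rownames(cn$cn) %||% as.character(seq_len(nrow(cn$cn)))
  out <- tibble::tibble(cell = cells)
  for (g in seq_len(nrow(genes))) {
    hit <- wins$chrom == genes$chrom[g] &
      wins$start < genes$end[g] & wins$end > genes$start[g]
    if (!any(hit)) {
      warning("gene ", genes$gene[g],
              " overlaps no retained window; returning NA")
      out[[genes$gene[g]]] <- NA_real_
    } else {
      out[[genes$gene[g]]] <- unname(rowMeans(cn$cn[, hit, drop = FALSE]))
    }
  }
  out
}

#' Classify a focal amplification from its per-cell copy numbers
#'
#' ecDNA segregates randomly at mitosis, so ecDNA amplifications show both an
#' elevated mean copy number and inflated cell-to-cell variance, unlike
#' chromosomal (HSR-like) amplifications. The decision rule is:
#' ecDNA-like iff `mean >= 4` and `variance/mean >= 2.5` (both inclusive);
#' amplified-non-ecDNA iff `mean >= 4` and `variance/mean < 2.5`;
#' otherwise not-amplified. With fewer than `min_cells` values the call is
#' indeterminate.
#'
#' @param cn_values Numeric vector of per-cell copy numbers for one region.
#' @param min_cells Minimum number of cells for a determinate call.
#' @param region Optional region label.
#' @return A one-row tibble: `region`, `n_cells`, `mean_cn`,
#'   `var_mean_ratio`, `class`.
#' @examples
#' classify_amplicon(rep(10, 50))$class              # amplified-non-ecDNA
#' classify_amplicon(rnbinom(500, mu = 20, size = 2) + 1)$class # ecDNA-like
#' @export
classify_amplicon <- function(cn_values, min_cells = 10, region = NA) {
  cn_values <- cn_values[!is.na(cn_values)]
  n <- length(cn_values)
  if (n < min_cells) {
    return(tibble::tibble(region = region, n_cells = n,
                          mean_cn = NA_real_, var_mean_ratio = NA_real_,
                          class = "indeterminate"))
  }
  m <- mean(cn_values)
  vm <- if (m > 0) var(cn_values) / m else 0
  cls <- if (m >= 4 && vm >= 2.5) "ecDNA-like"
         else if (m >= 4) "amplified-non-ecDNA"
         else "not-amplified"
  tibble::tibble(region = region, n_cells = n, mean_cn = m,
                 var_mean_ratio = vm, class = cls)
}

#' Copy-number correlation between two amplified genes
#'
#' Two conventions are supported: `"all-cells-log"` computes the Pearson
#' correlation of `log1p` copy numbers over all cells (the cell-line
#' analysis); `"amplified-only"` computes it on raw copy numbers restricted
#' to cells where both genes are amplified (`CN >= 4`; the tumour analysis).
#'
#' @param gene_cn A tibble from [gene_copy_number()] (column `cell` plus one
#'   column per gene).
#' @param genes Character vector of two gene column names.
#' @param mode `"all-cells-log"` or `"amplified-only"`.
#' @return A one-row tibble: `gene1`, `gene2`, `mode`, `n` (qualifying
#'   cells), `r`, `p`. With fewer than 3 qualifying cells `r` and `p` are
#'   `NA` and `n` reports the count.
#' @export
amplicon_correlation <- function(gene_cn, genes,
                                 mode = c("all-cells-log", "amplified-only")) {
  mode <- match.arg(mode)
  stopifnot(length(genes) == 2, all(genes %in% names(gene_cn)))
  x <- gene_cn[[genes[1]]]
  y <- gene_cn[[genes[2]]]
  ok <- !is.na(x) & !is.na(y)
  if (mode == "amplified-only") ok <- ok & x >= 4 & y >= 4
  x <- x[ok]; y <- y[ok]
  base <- tibble::tibble(gene1 = genes[1], gene2 = genes[2], mode = mode,
                         n = length(x), r = NA_real_, p = NA_real_)
  if (length(x) < 3) return(base)
  if (mode == "all-cells-log") { x <- log1p(x); y <- log1p(y) }
  if (var(x) == 0 || var(y) == 0) return(base)
  ct <- cor.test(x, y)
  base$r <- unname(ct$estimate)
  base$p <- ct$p.value
  base
}
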