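# Shared fixtures built in code.

# Wide per-division matrix of daughter-1 copies for both species.
divisions_wide <- function(parent, params, n, seed = NULL) {
  d <- segregate_divisions(parent, params, n = n, seed = seed)
  list(
    n1_d1 = d$n_daughter1[d$species == 1],
    n1_d2 = d$n_daughter2[d$species == 1],
    n2_d1 = d$n_daughter1[d$species == 2],
    n2_d2 = d$n_daughter2[d$species == 2])
}

# Chi-square goodness of fit of integer draws against Binomial(size, 1/2),
# pooling tail bins so expected counts stay above 5.
binomial_gof_p <- function(x, size) {
  probs <- dbinom(0:size, size, 0.5)
  expected <- probs * length(x)
  lo <- min(which(cumsum(expected) > 5)) - 1
  hi <- size - lo
  bins <- pmin(pmax(x, lo), hi)
  lev <- lo:hi
  obs <- tabulate(factor(bins, levels = lev), nbins = length(lev))
  p <- probs
  p[lo + 1] <- sum(probs[1:(lo + 1)])
  p[hi + 1] <- sum(probs[(hi + 1):(size + 1)])
  p <- p[(lo:hi) + 1]
  suppressWarnings(stats::chisq.test(obs, p = p / sum(p))$p.value)
}

# Two-sample chi-square homogeneity test for integer draws (KS is unreliable
# with heavy ties); pools sparse tail bins.
two_sample_gof_p <- function(x, y) {
  lev <- seq(min(x, y), max(x, y))
  tx <- tabulate(factor(x, levels = lev), nbins = length(lev))
  ty <- tabulate(factor(y, levels = lev), nbins = length(lev))
  tot <- tx + ty
  keep <- tot >= 10
  if (any(!keep)) {
    tx <- c(sum(tx[!keep]), tx[keep])
    ty <- c(sum(ty[!keep]), ty[keep])
  }
  suppressWarnings(stats::chisq.test(rbind(tx, ty))$p.value)
}

# Flat synthetic windowed count matrix: every window identical counts, equal
# widths, GC varying so neighbour sets are well-defined.
flat_counts_fixture <- function(n_cells = 3, n_windows = 150, count = 300,
                                seed = 1) {
  withr::with_seed(seed, {
    windows <- tibble::tibble(
      chrom = "chr1",
      start = as.integer((seq_len(n_windows) - 1) * 3e6),
      end = as.integer(seq_len(n_windows) * 3e6),
      gc = runif(n_windows, 0.35, 0.6),
      blacklisted = FALSE)
    counts <- matrix(count, nrow = n_cells, ncol = n_windows)
    rownames(counts) <- paste0("cell", seq_len(n_cells))
    list(counts = counts, windows = windows)
  })
}
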