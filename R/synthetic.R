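#' Describe a focal amplification to embed in synthetic counts
#'
#' @param tiles Integer range of 1-Mb tiles covered by the amplicon.
#' @param cn Per-cell copy-number source: a single number (constant,
#'   HSR-like), a numeric vector with one copy number per cell (e.g.
#'   simulator leaf states, ecDNA-like), or a list `list(mean =, size =)`
#'   for negative-binomial per-cell copy numbers.
#' @param label Region label used in the truth table.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(tiles, cn, label = "amplicon") {
  stopifnot(length(tiles) >= 1, all(tiles >= 1), all(tiles == floor(tiles)))
  structure(list(tiles = as.integer(tiles), cn = cn, label = label),
            class = "amplicon_spec")
}

#' Generate a synthetic single-cell windowed insertion-count matrix
#'
#' Emulates the windowed counts derived from single-cell ATAC data on which
#' copy-number calling operates: Poisson background whose per-tile rate
#' follows a smooth quadratic GC effect, per-cell depth variation, and
#' optional embedded focal amplifications whose per-cell copy numbers come
#' from an [amplicon_spec()]. Tiles are 1 Mb; the emitted windows are 3-Mb
#' sliding windows moving in 1-Mb steps (window counts are rolling sums of
#' tile counts, window GC the mean tile GC), matching the geometry the
#' copy-number caller assumes.
#'
#' @param n_cells Number of cells.
#' @param n_tiles Number of 1-Mb tiles (windows = `n_tiles - 2`).
#' @param amplicons List of [amplicon_spec()]s; tile ranges must not overlap.
#' @param depth Expected background insertions per cell (before depth
#'   variation).
#' @param gc_coef Quadratic log-rate GC coefficients `c(linear, quadratic)`
#'   applied to centred GC.
#' @param depth_sd Standard deviation of per-cell log-normal depth factors.
#' @param seed Optional integer seed.
#' @return A list: `counts` (sparse cells x windows `dgCMatrix`), `windows`
#'   (tibble `chrom`, `start`, `end`, `gc`, `blacklisted`), `truth` (tibble
#'   `cell`, one column of true copy number per amplicon), `tile_cn`
#'   (true per-tile, per-cell CN used to scale rates).
#' @examples
#' syn <- gen_counts_matrix(n_cells = 10, n_tiles = 120, seed = 1)
#' dim(syn$counts)
#' @export
gen_counts_matrix <- function(n_cells, n_tiles = 3000, amplicons = list(),
                              depth = 5000, gc_coef = c(1.5, -4),
                              depth_sd = 0.3, seed = NULL) {
  stopifnot(n_cells >= 1, n_tiles >= 5)
  covered <- integer(0)
  for (a in amplicons) {
    stopifnot(inherits(a, "amplicon_spec"))
    if (max(a$tiles) > n_tiles) {
      stop("amplicon `", a$label, "` exceeds the tile range", call. = FALSE)
    }
    if (length(intersect(covered, a$tiles)) > 0) {
      stop("amplicon specs overlap", call. = FALSE)
    }
    covered <- c(covered, a$tiles)
  }
  with_seed(seed, {
    # smooth, autocorrelated GC along the chromosome (isochore-like), so a
    # window's GC is representative of its constituent tiles
    phase <- runif(1, 0, 2 * pi)
    period <- runif(1, 30, 45)
    tile_gc <- 0.475 +
      0.085 * sin(2 * pi * seq_len(n_tiles) / period + phase) +
      rnorm(n_tiles, 0, 0.004)
    tile_gc <- pmin(pmax(tile_gc, 0.30), 0.65)
    gcc <- tile_gc - mean(tile_gc)
    w <- exp(gc_coef[1] * gcc + gc_coef[2] * gcc^2)
    w <- w / sum(w)
    cell_depth <- depth * rlnorm(n_cells, 0, depth_sd)
    # per-cell true CN per tile (diploid background = 2)
    tile_cn <- matrix(2, nrow = n_cells, ncol = n_tiles)
    truth <- tibble::tibble(cell = paste0("cell", seq_len(n_cells)))
    for (a in amplicons) {
      cn <- amplicon_cn(a, n_cells)
      tile_cn[, a$tiles] <- cn
      truth[[a$label]] <- cn
    }
    lambda <- (cell_depth %o% w) * tile_cn / 2
    tiles <- matrix(rpois(n_cells * n_tiles, lambda),
                    nrow = n_cells, ncol = n_tiles)
    # 3-tile rolling sums -> sliding 3 Mb windows stepping 1 Mb
    n_win <- n_tiles - 2
    counts <- tiles[, 1:n_win, drop = FALSE] +
      tiles[, 2:(n_win + 1), drop = FALSE] +
      tiles[, 3:(n_win + 2), drop = FALSE]
    win_gc <- (tile_gc[1:n_win] + tile_gc[2:(n_win + 1)] +
                 tile_gc[3:(n_win + 2)]) / 3
    rownames(counts) <- truth$cell
    windows <- tibble::tibble(
      chrom = "chr1",
      start = as.integer((seq_len(n_win) - 1) * 1e6),
      end = as.integer((seq_len(n_win) - 1) * 1e6 + 3e6),
      gc = win_gc,
      blacklisted = FALSE)
    list(counts = Matrix::Matrix(counts, sparse = TRUE),
         windows = windows, truth = truth, tile_cn = tile_cn)
  })
}

amplicon_cn <- function(spec, n_cells) {
  cn <- spec$cn
  if (is.list(cn)) {
    stopifnot(all(c("mean", "size") %in% names(cn)))
    return(rnbinom(n_cells, mu = cn$mean, size = cn$size))
  }
  if (length(cn) == 1) return(rep(as.numeric(cn), n_cells))
  if (length(cn) != n_cells) {
    stop("per-cell copy-number vector must have one value per cell",
         call. = FALSE)
  }
  as.numeric(cn)
}

#' Generate synthetic daughter-pair FISH measurements
#'
#' Simulates mitotic divisions under a segregation rule and converts the
#' inherited copies into signal units with multiplicative log-normal
#' measurement noise, emulating integrated-intensity FISH readouts of
#' daughter-cell pairs.
#'
#' @param n_pairs Number of pairs.
#' @param copies Parental copy numbers, length 2.
#' @param params A [coseg_params()] describing the segregation rule.
#' @param fusion_fraction Fused-molecule fraction recorded on every pair
#'   (used by [fusion_null()]).
#' @param noise_sd Standard deviation of the log-normal signal noise
#'   (0 = noiseless).
#' @param condition Condition label.
#' @param seed Optional integer seed.
#' @return A long tibble with columns `pair_id`, `species`, `signal_d1`,
#'   `signal_d2`, `fusion_fraction`, `condition` (empty when `n_pairs = 0`).
#' @examples
#' gen_daughter_pairs(3, params = coseg_params(model = "fraction_coupled",
#'                    coupled_fraction = 1), seed = 1)
#' @export
gen_daughter_pairs <- function(n_pairs, copies = c(100, 100),
                               params = coseg_params(), fusion_fraction = 0,
                               noise_sd = 0.1, condition = "synthetic",
                               seed = NULL) {
  empty <- tibble::tibble(
    pair_id = integer(), species = integer(),
    signal_d1 = numeric(), signal_d2 = numeric(),
    fusion_fraction = numeric(), condition = character())
  if (n_pairs == 0) return(empty)
  copies <- check_parent(copies)
  with_seed(seed, {
    div <- segregate_divisions(copies, params, n = n_pairs)
    noise <- function(n) exp(rnorm(n, 0, noise_sd))
    div %>%
      dplyr::transmute(
        pair_id = .data$division,
        species = .data$species,
        signal_d1 = .data$n_daughter1 * noise(dplyr::n()),
        signal_d2 = .data$n_daughter2 * noise(dplyr::n()),
        fusion_fraction = fusion_fraction,
        condition = condition)
  })
}

#' Generate observed summary statistics at a known parameter set
#'
#' Runs one forward simulation at `theta` under the inference conventions
#' (no death, `lambda_base = 0.5`, neutral ecDNA-free cells) and returns its
#' co-occurrence / correlation pair as an [observed_stats()] target together
#' with the generating parameters, for parameter-recovery experiments.
#'
#' @param theta Named list or one-row data frame: `s_indiv`, `s_plus_plus`,
#'   `gamma`.
#' @param sim_cells Population size to simulate.
#' @param m_abc Co-occurrence threshold (strict `>`).
#' @param k_init Founder copies per species.
#' @param seed Optional integer seed.
#' @param max_retries Retries (fresh substream) if a simulation goes extinct
#'   or yields an undefined correlation.
#' @return A list: `obs` ([observed_stats()]), `theta`, `summary` (the full
#'   [summarize_population()] row), `retries`.
#' @export
gen_observed_stats <- function(theta, sim_cells = 20000, m_abc = 2,
                               k_init = 5, seed = NULL, max_retries = 5) {
  theta <- as.list(theta)
  stopifnot(all(c("s_indiv", "s_plus_plus", "gamma") %in% names(theta)))
  config <- abc_config(sim_cells = sim_cells, k_init = k_init, m_abc = m_abc)
  for (try in 0:max_retries) {
    smry <- with_seed(if (is.null(seed)) NULL else seed + try,
                      abc_simulate(theta, config))
    if (smry$n_cells > 0 && smry$correlation_defined) {
      return(list(
        obs = observed_stats(smry$co_occurrence, smry$correlation,
                             label = "synthetic"),
        theta = theta, summary = smry, retries = try))
    }
  }
  stop("simulation degenerate after ", max_retries, " retries", call. = FALSE)
}
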