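#' Per-pair inherited proportions from daughter-pair signal tables
#'
#' Converts a long table of per-species FISH signal in each daughter of a
#' mitotic pair into per-pair inherited proportions
#' `p_j = signal_d1_j / (signal_d1_j + signal_d2_j)`. Pairs in which either
#' species has zero total signal are excluded and counted.
#'
#' @param pairs A data frame with columns `pair_id`, `species` (1 or 2),
#'   `signal_d1`, `signal_d2`, and optionally `fusion_fraction` and
#'   `condition`.
#' @return A tibble with one row per retained pair: `pair_id`, `p1`, `p2`,
#'   `total1`, `total2`, plus any `fusion_fraction` / `condition` carried
#'   through; the number of excluded pairs is attached as attribute
#'   `n_excluded`.
#' @export
pair_proportions <- function(pairs) {
  stopifnot(all(c("pair_id", "species", "signal_d1", "signal_d2") %in%
                  names(pairs)))
  if (any(pairs$signal_d1 < 0 | pairs$signal_d2 < 0, na.rm = TRUE)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  extra <- intersect(c("fusion_fraction", "condition"), names(pairs))
  wide <- pairs %>%
    dplyr::mutate(total = .data$signal_d1 + .data$signal_d2,
                  p = .data$signal_d1 / .data$total) %>%
    dplyr::select(dplyr::all_of(c("pair_id", "species", "p", "total", extra))) %>%
    tidyr::pivot_wider(names_from = "species", values_from = c("p", "total"),
                       names_sep = "")
  ok <- is.finite(wide$p1) & is.finite(wide$p2)
  out <- wide[ok, ]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Daughter-pair co-segregation correlation
#'
#' Pearson correlation between the inherited proportions of the two species
#' across pairs, taken from daughter 1 by convention (the magnitude is
#' invariant to the choice because the daughter-2 proportion is `1 - p`).
#'
#' @param pairs Either a long signal table (see [pair_proportions()]) or a
#'   proportions tibble with columns `p1`, `p2`.
#' @return A one-row tibble: `r`, `p`, `n`, `defined`. Constant proportions
#'   give `defined = FALSE` with `NA` statistics.
#' @export
coseg_correlation <- function(pairs) {
  props <- as_proportions(pairs)
  n <- nrow(props)
  if (n < 3) stop("need at least 3 pairs for a correlation", call. = FALSE)
  if (var(props$p1) == 0 || var(props$p2) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                          defined = FALSE))
  }
  ct <- cor.test(props$p1, props$p2)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                 defined = TRUE)
}

as_proportions <- function(pairs) {
  if (all(c("p1", "p2") %in% names(pairs))) return(tibble::as_tibble(pairs))
  pair_proportions(pairs)
}

#' Covalent-fusion null distribution of the daughter-pair correlation
#'
#' Tests whether an observed co-segregation correlation exceeds what covalent
#' fusion between the two ecDNA species can explain alone. For every observed
#' pair, `n_events` divisions are simulated under the fraction-coupled rule
#' with the coupled fraction set to that pair's observed fused-molecule
#' fraction (fused copies perfectly co-segregate, the rest split
#' independently). Event `e` across pairs forms null dataset `e`; the null
#' distribution is the correlation of each dataset. The observed correlation
#' is compared to the null mean by Fisher z (two-sided by default).
#'
#' Signals are converted to integer pseudo-copies by scaling each pair's
#' larger species total to `total_copies` (FISH intensity is not calibrated
#' to molecule counts; this preserves within-pair relative abundance).
#'
#' @param pairs A long signal table or proportions tibble carrying
#'   `fusion_fraction` and species totals.
#' @param n_events Simulated divisions per observed pair (default 20).
#' @param total_copies Pseudo-copy total used in the signal conversion.
#' @param seed Optional integer seed.
#' @return A list of class `fusion_null`: `observed` (the observed
#'   correlation row), `null_r` (numeric vector, one correlation per
#'   simulated dataset), `z`, `p`, `n_pairs`, `n_events`.
#' @export
fusion_null <- function(pairs, n_events = 20, total_copies = 200,
                        seed = NULL) {
  props <- as_proportions(pairs)
  if (!"fusion_fraction" %in% names(props) ||
      any(is.na(props$fusion_fraction))) {
    stop("every pair needs a `fusion_fraction`", call. = FALSE)
  }
  n_pairs <- nrow(props)
  obs <- coseg_correlation(props)
  scale <- total_copies / pmax(props$total1, props$total2)
  # parent copies: the doubled complement is the observed pseudo-copy total
  n1 <- pmax(1L, as.integer(round(props$total1 * scale / 2)))
  n2 <- pmax(1L, as.integer(round(props$total2 * scale / 2)))
  with_seed(seed, {
    null_r <- vapply(seq_len(n_events), function(e) {
      m <- segregate_matrix(n1, n2, "fraction_coupled",
                            props$fusion_fraction)
      p1 <- m[, "n1_d1"] / (m[, "n1_d1"] + m[, "n1_d2"])
      p2 <- m[, "n2_d1"] / (m[, "n2_d1"] + m[, "n2_d2"])
      if (var(p1) == 0 || var(p2) == 0) return(NA_real_)
      cor(p1, p2)
    }, numeric(1))
    null_mean <- mean(null_r, na.rm = TRUE)
    z <- (atanh(clamp_r(obs$r)) - atanh(clamp_r(null_mean))) *
      sqrt(n_pairs - 3)
    p <- 2 * pnorm(-abs(z))
    structure(
      list(observed = obs, null_r = null_r, null_mean = null_mean,
           z = z, p = p, n_pairs = n_pairs, n_events = n_events),
      class = "fusion_null")
  })
}

clamp_r <- function(r, eps = 1e-12) max(min(r, 1 - eps), -1 + eps)

#' @export
print.fusion_null <- function(x, ...) {
  cat("<fusion_null> observed R = ", format(x$observed$r, digits = 3),
      " vs fusion-only null mean R = ", format(x$null_mean, digits = 3),
      " (", x$n_events, " events x ", x$n_pairs, " pairs)\n",
      "  Fisher z = ", format(x$z, digits = 4),
      ", two-sided p = ", format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Compare two Pearson correlations by Fisher z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a one- or
#' two-sided normal p-value (one-sided tests `r1 > r2`).
#'
#' @param r1,r2 The correlations, strictly inside (-1, 1).
#' @param n1,n2 Their sample sizes (at least 4).
#' @param sided `"two"` (default) or `"one"`.
#' @return A one-row tibble: `z`, `p`.
#' @examples
#' fisher_z_compare(0.5, 53, 0.0, 53) # z = atanh(0.5) * 5
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| = 1: Fisher transform is infinite", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (sided == "two") 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
  tibble::tibble(z = z, p = p)
}

#' Expected daughter-pair correlation as a function of the coupled fraction
#'
#' Simulates `n_pairs` divisions at each value of the coupled-fraction grid
#' and records the correlation between the daughters' inherited proportions;
#' the resulting curve maps an observed correlation to an implied
#' co-segregation level (approximately the identity for large copy numbers).
#'
#' @param copies Parental copy number used for both species.
#' @param phi_grid Coupled-fraction grid in `[0, 1]`.
#' @param n_pairs Simulated pairs per grid point.
#' @param seed Optional integer seed.
#' @return A tibble: `phi`, `expected_r`, `n_pairs`.
#' @examples
#' coseg_calibration_curve(copies = 100, phi_grid = c(0, 0.5, 1),
#'                         n_pairs = 500, seed = 1)
#' @export
coseg_calibration_curve <- function(copies = 100,
                                    phi_grid = seq(0, 1, by = 0.25),
                                    n_pairs = 10000, seed = NULL) {
  stopifnot(all(phi_grid >= 0 & phi_grid <= 1), copies >= 1, n_pairs >= 10)
  with_seed(seed, {
    purrr::map_dfr(phi_grid, function(phi) {
      m <- segregate_matrix(rep.int(copies, n_pairs),
                            rep.int(copies, n_pairs),
                            "fraction_coupled", phi)
      p1 <- m[, "n1_d1"] / (2 * copies)
      p2 <- m[, "n2_d1"] / (2 * copies)
      r <- if (var(p1) == 0 || var(p2) == 0) NA_real_ else cor(p1, p2)
      tibble::tibble(phi = phi, expected_r = r, n_pairs = n_pairs)
    })
  })
}
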