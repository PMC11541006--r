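#' Parameters of the birth-death ecDNA population simulation
#'
#' A growing population is founded by one cell carrying `k_init` copies of two
#' ecDNA species. Each cell's birth rate depends only on which species are
#' present: `lambda_1 = lambda_base * (1 + s)` where `s` is the selection
#' coefficient of the cell's presence class. Waiting times to division are
#' exponential with rate `lambda_1`; when `mu > 0` each cell also races an
#' exponential death clock with rate `mu`. At division the doubled copies are
#' partitioned by the rule in `coseg`.
#'
#' @param k_init Integer vector of length 2: founder copy number per species.
#' @param s_minus_minus Selection on cells carrying neither species.
#' @param s_minus_plus Selection on cells carrying only species 2.
#' @param s_plus_minus Selection on cells carrying only species 1.
#' @param s_plus_plus Selection (co-selection) on cells carrying both species.
#' @param lambda_base Base birth rate (per unit time), `> 0`.
#' @param mu Death rate (per unit time), `>= 0`.
#' @param coseg A [coseg_params()] object.
#' @param target_cells Stop once the population reaches this size.
#' @param target_time Stop at this absolute time. At least one of
#'   `target_cells` / `target_time` must be set; whichever is reached first
#'   applies, and cells mid-waiting-time at a time stop count as leaves.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(k_init = c(5, 5), s_plus_plus = 1,
#'            coseg = coseg_params(gamma = 1), target_cells = 1000)
#' @export
sim_params <- function(k_init = c(5, 5),
                       s_minus_minus = 0, s_minus_plus = 0,
                       s_plus_minus = 0, s_plus_plus = 0,
                       lambda_base = 0.5, mu = 0,
                       coseg = coseg_params(),
                       target_cells = NULL, target_time = NULL) {
  k_init <- check_parent(k_init)
  s <- c(s_minus_minus, s_plus_minus, s_minus_plus, s_plus_plus)
  if (any(!is.finite(s))) stop("selection coefficients must be finite",
                               call. = FALSE)
  if (any(1 + s <= 0)) {
    stop("all birth rates must be positive: need 1 + s > 0 for every class",
         call. = FALSE)
  }
  if (!is.numeric(lambda_base) || lambda_base <= 0) {
    stop("`lambda_base` must be > 0", call. = FALSE)
  }
  if (!is.numeric(mu) || mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  stopifnot(inherits(coseg, "coseg_params"))
  if (is.null(target_cells) && is.null(target_time)) {
    stop("set at least one of `target_cells` or `target_time`", call. = FALSE)
  }
  if (!is.null(target_cells) &&
      (target_cells < 1 || target_cells != floor(target_cells))) {
    stop("`target_cells` must be a positive integer", call. = FALSE)
  }
  if (!is.null(target_time) && target_time <= 0) {
    stop("`target_time` must be positive", call. = FALSE)
  }
  structure(
    list(k_init = k_init,
         s_minus_minus = s_minus_minus, s_minus_plus = s_minus_plus,
         s_plus_minus = s_plus_minus, s_plus_plus = s_plus_plus,
         lambda_base = lambda_base, mu = mu, coseg = coseg,
         target_cells = target_cells, target_time = target_time),
    class = "sim_params"
  )
}

#' Realised birth rate of a cell
#'
#' `lambda_1 = lambda_base * (1 + s)`, where `s` is chosen from the four
#' selection coefficients by the presence (copy number `> 0`) of each species.
#'
#' @param state Integer vector of length 2, copy numbers of the two species.
#' @param params A [sim_params()] object.
#' @return The birth rate, a positive scalar.
#' @examples
#' p <- sim_params(s_plus_minus = 0.2, target_cells = 10)
#' compute_birth_rate(c(3, 0), p) # 0.5 * 1.2
#' @export
compute_birth_rate <- function(state, params) {
  state <- check_parent(state)
  s <- selection_of(state, params)
  rate <- params$lambda_base * (1 + s)
  if (rate <= 0) stop("non-positive birth rate", call. = FALSE)
  rate
}

selection_of <- function(state, params) {
  if (state[1] > 0 && state[2] > 0) params$s_plus_plus
  else if (state[1] > 0) params$s_plus_minus
  else if (state[2] > 0) params$s_minus_plus
  else params$s_minus_minus
}

#' Simulate a growing ecDNA-carrying cell population
#'
#' Runs the continuous-time birth-death process of [sim_params()] from a
#' single founder (or a supplied set of founder cells) until the stop
#' condition, using the exact Gillespie direct method. Fully reproducible
#' given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @param founders Optional integer matrix (cells x 2) of founder states;
#'   defaults to a single cell at `params$k_init`.
#' @param start_time Absolute clock time at which the simulation starts
#'   (used by multi-phase schedules).
#' @param record_tree Record the lineage so the phylogeny can be extracted
#'   with [sim_tree()]. Refused above `tree_cap` cells.
#' @param record_trajectory Record population size and mean copy number after
#'   every event (see `$trajectory`).
#' @param tree_cap Maximum `target_cells` for which lineage recording is
#'   allowed (full lineage retention is memory-hungry).
#' @return An object of class `ecdna_sim`: a list with `leaves` (tibble
#'   `cell`, `k1`, `k2`), `n_cells`, `final_time`, `extinct` flag, `params`,
#'   and optionally `trajectory` (tibble) and `lineage`. An extinct
#'   population is a valid result with zero leaves, not an error.
#' @examples
#' sim <- simulate_population(
#'   sim_params(k_init = c(5, 5), target_cells = 200), seed = 1)
#' summarize_population(sim)
#' @export
simulate_population <- function(params, seed = NULL, founders = NULL,
                                start_time = 0,
                                record_tree = FALSE,
                                record_trajectory = FALSE,
                                tree_cap = 10000) {
  stopifnot(inherits(params, "sim_params"))
  target_cells <- params$target_cells %||% .Machine$integer.max
  target_time <- params$target_time %||% Inf
  if (record_tree && target_cells > tree_cap) {
    stop("lineage recording refused above `tree_cap` cells; raise the cap ",
         "explicitly if you really want the full lineage", call. = FALSE)
  }
  if (is.null(founders)) {
    founders <- matrix(params$k_init, nrow = 1)
  }
  founders <- matrix(as.integer(founders), ncol = 2)
  s <- c(params$s_minus_minus, params$s_plus_minus,
         params$s_minus_plus, params$s_plus_plus)
  coseg <- params$coseg
  coef <- if (coseg$model == "fraction_coupled") coseg$coupled_fraction
          else coseg$gamma
  res <- with_seed(seed,
    cpp_simulate_population(
      founders[, 1], founders[, 2], s, params$lambda_base, params$mu,
      model_code(coseg$model), coef, coseg$anchor_species,
      as.integer(target_cells), as.numeric(target_time),
      as.numeric(start_time), record_tree, record_trajectory))
  leaves <- tibble::tibble(
    cell = seq_len(res$n_cells),
    k1 = res$k1, k2 = res$k2)
  out <- list(
    leaves = leaves,
    n_cells = res$n_cells,
    final_time = res$final_time,
    extinct = res$extinct,
    params = params,
    seed = seed)
  if (record_trajectory) {
    out$trajectory <- tibble::as_tibble(res$trajectory)
  }
  if (record_tree) out$lineage <- res$lineage
  structure(out, class = "ecdna_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecdna_sim <- function(x, ...) {
  cat("<ecdna_sim> ", x$n_cells, " cells at time ",
      format(x$final_time, digits = 4),
      if (x$extinct) " (extinct)" else "", "\n", sep = "")
  if (x$n_cells > 0) {
    cat("  mean copies: species 1 = ", format(mean(x$leaves$k1), digits = 4),
        ", species 2 = ", format(mean(x$leaves$k2), digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Extract the lineage tree of a simulation
#'
#' Builds an [ape::phylo] tree over the surviving cells from a simulation run
#' with `record_tree = TRUE`. Lineages that died before the stop condition are
#' pruned. Edge lengths are the waiting times along each cell's life span;
#' leaf labels carry the leaf copy states as `cell<i>_k1_k2`.
#'
#' @param sim An `ecdna_sim` with a recorded lineage.
#' @return An `ape` `phylo` object (or a single-tip degenerate tree).
#' @export
sim_tree <- function(sim) {
  stopifnot(inherits(sim, "ecdna_sim"))
  if (is.null(sim$lineage)) {
    stop("simulation was run without `record_tree = TRUE`", call. = FALSE)
  }
  lin <- sim$lineage
  n <- length(lin$parent)
  t_end <- ifelse(is.na(lin$t_end), sim$final_time, lin$t_end)
  # keep cells with at least one surviving descendant (or alive themselves)
  keep <- as.logical(lin$alive)
  children <- split(seq_len(n), factor(lin$parent + 1L, levels = seq_len(n)))
  order_desc <- rev(seq_len(n))  # children always have larger index
  for (i in order_desc) {
    p <- lin$parent[i] + 1L
    if (keep[i] && p > 0) keep[p] <- TRUE
  }
  if (!any(keep)) stop("population extinct: no surviving lineage",
                       call. = FALSE)
  # newick assembly, collapsing single-child chains (a divided cell with one
  # surviving daughter contributes only branch length)
  build <- function(i) {
    kids <- children[[i]]
    kids <- kids[keep[kids]]
    len <- t_end[i] - lin$t_birth[i]
    if (length(kids) == 0) {
      lab <- paste0("cell", i, "_", lin$k1[i], "_", lin$k2[i])
      return(list(str = lab, len = len))
    }
    subs <- lapply(kids, build)
    if (length(subs) == 1) {
      return(list(str = subs[[1]]$str, len = len + subs[[1]]$len))
    }
    inner <- paste(vapply(subs, function(s) {
      paste0(s$str, ":", format(s$len, digits = 10))
    }, character(1)), collapse = ",")
    list(str = paste0("(", inner, ")"), len = len)
  }
  roots <- which(lin$parent == -1L & keep)
  if (length(roots) == 1) {
    b <- build(roots)
    nwk <- paste0(b$str, ";")
  } else {
    subs <- lapply(roots, build)
    inner <- paste(vapply(subs, function(s)
      paste0(s$str, ":", format(s$len, digits = 10)), character(1)),
      collapse = ",")
    nwk <- paste0("(", inner, ");")
  }
  ape::read.tree(text = nwk)
}

#' Population summary statistics
#'
#' Computes the two co-assortment summaries over leaf copy states:
#' co-occurrence `C = mean(I(k1 > m & k2 > m))` and the Pearson correlation
#' `rho` of per-cell copy numbers (on raw copies, or on `log1p` copies for
#' comparison against single-cell ATAC-derived observations), plus the
#' pure/mix/free subpopulation fractions and per-species mean copy number.
#'
#' @param leaves A tibble/data.frame with columns `k1`, `k2` (one row per
#'   cell), or an `ecdna_sim` object.
#' @param m Copy-number threshold for co-occurrence (strict `>`).
#' @param transform `"raw"` (default) or `"log"` (`log1p`) before the
#'   correlation.
#' @return A one-row tibble: `n_cells`, `co_occurrence`, `correlation`,
#'   `correlation_defined`, `pure`, `mix`, `free`, `mean_k1`, `mean_k2`,
#'   `m`, `transform`. `correlation` is `NA` with
#'   `correlation_defined = FALSE` when either species is constant.
#' @examples
#' leaves <- tibble::tibble(k1 = c(2, 0, 1), k2 = c(3, 5, 1))
#' summarize_population(leaves, m = 1)$co_occurrence # 1/3
#' @export
summarize_population <- function(leaves, m = 1,
                                 transform = c("raw", "log")) {
  transform <- match.arg(transform)
  leaves <- as_leaves(leaves)
  if (nrow(leaves) == 0) stop("empty leaf set", call. = FALSE)
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  k1 <- leaves$k1
  k2 <- leaves$k2
  co <- mean(k1 > m & k2 > m)
  x <- if (transform == "log") log1p(k1) else as.numeric(k1)
  y <- if (transform == "log") log1p(k2) else as.numeric(k2)
  defined <- length(k1) >= 2 && var(x) > 0 && var(y) > 0
  rho <- if (defined) cor(x, y) else NA_real_
  fr <- subpopulation_fractions(leaves)
  tibble::tibble(
    n_cells = nrow(leaves),
    co_occurrence = co,
    correlation = rho,
    correlation_defined = defined,
    pure = fr$pure, mix = fr$mix, free = fr$free,
    mean_k1 = mean(k1), mean_k2 = mean(k2),
    m = m, transform = transform)
}

as_leaves <- function(leaves) {
  if (inherits(leaves, "ecdna_sim")) return(leaves$leaves)
  stopifnot(is.data.frame(leaves), all(c("k1", "k2") %in% names(leaves)))
  leaves
}

#' Pure / mix / free subpopulation fractions
#'
#' Fractions of cells carrying exactly one species (pure), both species
#' (mix), or neither (free). The three fractions sum to one.
#'
#' @inheritParams summarize_population
#' @return A one-row tibble with columns `pure`, `mix`, `free`.
#' @examples
#' subpopulation_fractions(
#'   tibble::tibble(k1 = c(1, 2, 0, 0), k2 = c(1, 0, 0, 3)))
#' @export
subpopulation_fractions <- function(leaves) {
  leaves <- as_leaves(leaves)
  if (nrow(leaves) == 0) stop("empty leaf set", call. = FALSE)
  p1 <- leaves$k1 > 0
  p2 <- leaves$k2 > 0
  tibble::tibble(
    pure = mean(xor(p1, p2)),
    mix = mean(p1 & p2),
    free = mean(!p1 & !p2))
}

#' @method tidy ecdna_sim
#' @export
tidy.ecdna_sim <- function(x, ...) x$leaves

#' @method glance ecdna_sim
#' @export
glance.ecdna_sim <- function(x, m = 1, transform = "raw", ...) {
  if (x$n_cells == 0) {
    return(tibble::tibble(n_cells = 0L, extinct = TRUE,
                          final_time = x$final_time))
  }
  dplyr::mutate(summarize_population(x$leaves, m = m, transform = transform),
                extinct = x$extinct, final_time = x$final_time,
                .after = "n_cells")
}
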