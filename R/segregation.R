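#' Co-segregation parameters for a cell division
#'
#' Bundles the segregation rule applied when a cell divides and its doubled
#' ecDNA complement is partitioned between the two daughters.
#'
#' Three rules are supported:
#' \describe{
#'   \item{`element_level`}{The anchor species splits
#'     `Binomial(2*N_anchor, 1/2)`. The other species follows it: a
#'     deterministic coupled share `floor(gamma * 2*N_other * n_anchor_i /
#'     (2*N_anchor))` goes to each daughter `i` and the remaining copies split
#'     binomially. `gamma = 0` is fully independent segregation, `gamma = 1`
#'     proportional co-segregation.}
#'   \item{`cell_level`}{Both species split binomially and independently;
#'     with probability `gamma` the larger half of the other species is placed
#'     in the daughter that received the larger anchor half (extreme
#'     copy-number correlation), with probability `1 - gamma` in the opposite
#'     daughter. `gamma = 0.5` reproduces independent random segregation.}
#'   \item{`fraction_coupled`}{A fraction `coupled_fraction` of each species'
#'     doubled copies is distributed at one shared random ratio drawn once per
#'     division; the rest splits independently. Setting the fraction to an
#'     observed fused-molecule fraction gives the covalent-fusion null.}
#' }
#'
#' @param gamma Co-segregation coefficient in `[0, 1]` (element- and
#'   cell-level rules).
#' @param model One of `"element_level"`, `"cell_level"`,
#'   `"fraction_coupled"`.
#' @param coupled_fraction Shared-ratio fraction in `[0, 1]`
#'   (fraction-coupled rule only).
#' @param anchor_species Which species (1 or 2) conditions the other's split.
#' @return An object of class `coseg_params`.
#' @examples
#' coseg_params(gamma = 0.8)
#' coseg_params(model = "fraction_coupled", coupled_fraction = 0.3)
#' @export
coseg_params <- function(gamma = 0,
                         model = c("element_level", "cell_level",
                                   "fraction_coupled"),
                         coupled_fraction = 0,
                         anchor_species = 1) {
  model <- match.arg(model)
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("`gamma` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(coupled_fraction) || length(coupled_fraction) != 1 ||
      is.na(coupled_fraction) || coupled_fraction < 0 ||
      coupled_fraction > 1) {
    stop("`coupled_fraction` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!anchor_species %in% c(1, 2)) {
    stop("`anchor_species` must be 1 or 2", call. = FALSE)
  }
  structure(
    list(gamma = gamma, model = model,
         coupled_fraction = coupled_fraction,
         anchor_species = as.integer(anchor_species)),
    class = "coseg_params"
  )
}

#' @export
print.coseg_params <- function(x, ...) {
  coef <- if (x$model == "fraction_coupled") {
    paste0("coupled_fraction = ", x$coupled_fraction)
  } else {
    paste0("gamma = ", x$gamma)
  }
  cat("<coseg_params> ", x$model, ", ", coef,
      ", anchor species ", x$anchor_species, "\n", sep = "")
  invisible(x)
}

model_code <- function(model) {
  match(model, c("element_level", "cell_level", "fraction_coupled"))
}

check_parent <- function(parent) {
  if (length(parent) != 2 || any(is.na(parent)) || any(parent < 0) ||
      any(parent != floor(parent))) {
    stop("`parent` must be two non-negative integer copy numbers",
         call. = FALSE)
  }
  as.integer(parent)
}

#' Simulate cell divisions under a segregation rule
#'
#' Partitions the doubled ecDNA complement of a parent cell between two
#' daughters, `n` independent times. Copy conservation
#' (`d1 + d2 = 2 * parent`) holds exactly for every division and species.
#'
#' @param parent Integer vector of length 2: parental copy number of each
#'   ecDNA species.
#' @param params A [coseg_params()] object.
#' @param n Number of independent divisions to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per division and species:
#'   `division`, `species`, `n_daughter1`, `n_daughter2`,
#'   `coupled_part1`, `coupled_part2` (coupled parts are `NA` for species 1
#'   and for the cell-level rule, where no deterministic share exists).
#' @examples
#' segregate_divisions(c(10, 10), coseg_params(gamma = 1), n = 3, seed = 1)
#' @export
segregate_divisions <- function(parent, params = coseg_params(), n = 1,
                                seed = NULL) {
  stopifnot(inherits(params, "coseg_params"))
  parent <- check_parent(parent)
  coef <- if (params$model == "fraction_coupled") params$coupled_fraction
          else params$gamma
  a <- params$anchor_species
  p_anchor <- parent[a]
  p_other <- parent[3 - a]
  m <- with_seed(seed,
    cpp_segregate(rep.int(p_anchor, n), rep.int(p_other, n),
                  model_code(params$model), coef))
  # columns 1:2 anchor daughters, 3:4 other daughters, 5:6 coupled parts
  sp1 <- if (a == 1) m[, 1:2, drop = FALSE] else m[, 3:4, drop = FALSE]
  sp2 <- if (a == 1) m[, 3:4, drop = FALSE] else m[, 1:2, drop = FALSE]
  coup <- m[, 5:6, drop = FALSE]
  other_idx <- 3 - a
  out <- tibble::tibble(
    division = rep(seq_len(n), times = 2),
    species = rep(1:2, each = n),
    n_daughter1 = as.integer(c(sp1[, 1], sp2[, 1])),
    n_daughter2 = as.integer(c(sp1[, 2], sp2[, 2])),
    coupled_part1 = rep(NA_real_, 2 * n),
    coupled_part2 = rep(NA_real_, 2 * n)
  )
  rows_other <- out$species == other_idx
  out$coupled_part1[rows_other] <- coup[, 1]
  out$coupled_part2[rows_other] <- coup[, 2]
  dplyr::arrange(out, .data$division, .data$species)
}

#' Single-division segregation rules
#'
#' Thin wrappers over [segregate_divisions()] fixing the rule; each returns
#' the partition of one division as a two-row tibble (one row per species).
#'
#' @inheritParams segregate_divisions
#' @return A tibble as in [segregate_divisions()] with `division = 1`.
#' @seealso [coseg_params()] for the rule definitions.
#' @examples
#' segregate_element_level(c(10, 10), coseg_params(gamma = 1), seed = 1)
#' @export
segregate_element_level <- function(parent, params, seed = NULL) {
  stopifnot(params$model == "element_level")
  segregate_divisions(parent, params, n = 1, seed = seed)
}

#' @rdname segregate_element_level
#' @export
segregate_cell_level <- function(parent, params, seed = NULL) {
  stopifnot(params$model == "cell_level")
  segregate_divisions(parent, params, n = 1, seed = seed)
}

#' @rdname segregate_element_level
#' @export
segregate_fraction_coupled <- function(parent, params, seed = NULL) {
  stopifnot(params$model == "fraction_coupled")
  segregate_divisions(parent, params, n = 1, seed = seed)
}

# Fast matrix interface used internally (daughter-pair simulation, tests):
# one division per row of (N1, N2, coef). Returns the cpp matrix.
segregate_matrix <- function(N1, N2, model, coef) {
  cpp_segregate(as.integer(N1), as.integer(N2), model_code(model),
                as.numeric(coef))
}
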