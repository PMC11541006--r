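#' One phase of a multi-phase simulation schedule
#'
#' A phase optionally overrides selection coefficients and the base birth
#' rate, optionally bottlenecks the population at entry (uniform sampling
#' without replacement), and runs until its stop condition.
#'
#' @param name Phase label (used in trajectory reports).
#' @param s_minus_minus,s_minus_plus,s_plus_minus,s_plus_plus Optional
#'   selection overrides; `NULL` keeps the incoming value.
#' @param lambda_base Optional base-birth-rate override.
#' @param bottleneck_sample Optional number of cells sampled uniformly at
#'   random (without replacement) to seed the phase.
#' @param target_cells,target_time Stop condition (first reached wins);
#'   `target_time` is on the global clock, which runs across phases.
#' @param bin_width Width of the time bins used for this phase in trajectory
#'   reports.
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(name,
                       s_minus_minus = NULL, s_minus_plus = NULL,
                       s_plus_minus = NULL, s_plus_plus = NULL,
                       lambda_base = NULL,
                       bottleneck_sample = NULL,
                       target_cells = NULL, target_time = NULL,
                       bin_width = 1) {
  if (is.null(target_cells) && is.null(target_time)) {
    stop("phase `", name, "`: set target_cells and/or target_time",
         call. = FALSE)
  }
  structure(
    list(name = name,
         s_minus_minus = s_minus_minus, s_minus_plus = s_minus_plus,
         s_plus_minus = s_plus_minus, s_plus_plus = s_plus_plus,
         lambda_base = lambda_base,
         bottleneck_sample = bottleneck_sample,
         target_cells = target_cells, target_time = target_time,
         bin_width = bin_width),
    class = "phase_spec")
}

#' A multi-phase treatment schedule
#'
#' @param base A [sim_params()] object providing the death rate, founder
#'   state, segregation rule and default selection; its own stop condition is
#'   ignored in favour of the phases'.
#' @param phases A list of [phase_spec()] objects, executed in order.
#' @param meta Optional named list of free-form metadata carried along.
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(base, phases, meta = list()) {
  stopifnot(inherits(base, "sim_params"), length(phases) >= 1,
            all(vapply(phases, inherits, logical(1), "phase_spec")))
  structure(list(base = base, phases = phases, meta = meta),
            class = "treatment_schedule")
}

#' Run a treatment schedule
#'
#' Executes the phases sequentially on the global clock, carrying surviving
#' cells (after any entry bottleneck) into each next phase with its parameter
#' overrides, and reports time-binned mean copy number per species and
#' population size.
#'
#' @param schedule A [treatment_schedule()].
#' @param seed Optional integer seed.
#' @return An object of class `ecdna_trajectory`: list with `bins` (tibble
#'   `phase`, `t_mid`, `mean_k1`, `mean_k2`, `n_cells`), `phase_ends`
#'   (per-phase end time, end size, extinct flag), `final_leaves` (tibble)
#'   and `extinct`. Extinction mid-schedule truncates the report and flags
#'   it; it is not an error.
#' @examples
#' \donttest{
#' sched <- preset_pemigatinib_pulse(scale = 0.01)
#' traj <- run_schedule(sched, seed = 1)
#' head(traj$bins)
#' }
#' @export
run_schedule <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  with_seed(seed, run_schedule_impl(schedule))
}

run_schedule_impl <- function(schedule) {
  base <- schedule$base
  founders <- matrix(base$k_init, nrow = 1)
  t0 <- 0
  bins <- list()
  ends <- list()
  extinct <- FALSE
  leaves <- NULL
  for (ph in schedule$phases) {
    if (!is.null(ph$bottleneck_sample)) {
      if (ph$bottleneck_sample > nrow(founders)) {
        stop("phase `", ph$name, "`: bottleneck (", ph$bottleneck_sample,
             ") exceeds population size (", nrow(founders), ")",
             call. = FALSE)
      }
      founders <- founders[sample.int(nrow(founders), ph$bottleneck_sample),
                           , drop = FALSE]
    }
    params <- sim_params(
      k_init = base$k_init,
      s_minus_minus = ph$s_minus_minus %||% base$s_minus_minus,
      s_minus_plus = ph$s_minus_plus %||% base$s_minus_plus,
      s_plus_minus = ph$s_plus_minus %||% base$s_plus_minus,
      s_plus_plus = ph$s_plus_plus %||% base$s_plus_plus,
      lambda_base = ph$lambda_base %||% base$lambda_base,
      mu = base$mu, coseg = base$coseg,
      target_cells = ph$target_cells, target_time = ph$target_time)
    sim <- simulate_population(params, founders = founders,
                               start_time = t0, record_trajectory = TRUE)
    bins[[ph$name]] <- bin_trajectory(sim$trajectory, ph$bin_width, ph$name)
    ends[[ph$name]] <- tibble::tibble(
      phase = ph$name, end_time = sim$final_time,
      end_cells = sim$n_cells, extinct = sim$extinct)
    t0 <- sim$final_time
    leaves <- sim$leaves
    if (sim$extinct) { extinct <- TRUE; break }
    founders <- cbind(sim$leaves$k1, sim$leaves$k2)
  }
  structure(
    list(bins = dplyr::bind_rows(bins),
         phase_ends = dplyr::bind_rows(ends),
         final_leaves = leaves,
         extinct = extinct,
         schedule = schedule),
    class = "ecdna_trajectory")
}

# Time-bin a per-event trajectory into contiguous bins of the given width,
# averaging the population mean copy number over the records in each bin.
bin_trajectory <- function(traj, width, phase) {
  traj <- tibble::as_tibble(traj)
  if (nrow(traj) == 0) return(tibble::tibble())
  lo <- floor(min(traj$time) / width) * width
  traj %>%
    dplyr::mutate(bin = lo + width * (floor((.data$time - lo) / width))) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(
      mean_k1 = mean(.data$mean_k1, na.rm = TRUE),
      mean_k2 = mean(.data$mean_k2, na.rm = TRUE),
      n_cells = .data$n_cells[dplyr::n()],
      .groups = "drop") %>%
    dplyr::transmute(phase = phase, t_mid = .data$bin + width / 2,
                     .data$mean_k1, .data$mean_k2, .data$n_cells)
}

#' @export
print.ecdna_trajectory <- function(x, ...) {
  cat("<ecdna_trajectory> ", nrow(x$phase_ends), " phases",
      if (x$extinct) " (extinct)" else "", "\n", sep = "")
  print(x$phase_ends)
  invisible(x)
}

#' @method tidy ecdna_trajectory
#' @export
tidy.ecdna_trajectory <- function(x, ...) x$bins

#' The pulsed FGFR2-inhibitor treatment schedule
#'
#' Four phases reproducing the pulsed pemigatinib protocol on a population
#' carrying an FGFR2 ecDNA (species 1, drug-targeted) and a MYC ecDNA
#' (species 2): a drug-free burn-in to 5,000 cells (`lambda_base = 0.5`,
#' mean death waiting time 2.5, `k_init = (10, 10)`, selection 0 / 0.15 /
#' 0.15 / 0.8), a first treatment (`s_plus_plus = s_plus_minus = -0.1`) to
#' 100,000 cells, a drug holiday at original selection with
#' `lambda_base = 0.4` to 1,200,000 cells entered through a 25,000-cell
#' bottleneck, and a second treatment entered through a 200,000-cell
#' bottleneck running until global time 110. Trajectories are binned at
#' width 5 before treatment and 1 afterwards.
#'
#' The protocol's death parameter of 2.5 is the mean death waiting time; the
#' simulator's death rate is therefore `1/2.5 = 0.4` (a death *rate* of 2.5
#' would dominate every attainable birth rate and the burn-in could never
#' grow). A `safety_cells` cap bounds the open-ended final phase.
#'
#' @param gamma Co-segregation coefficient used throughout.
#' @param scale Factor shrinking every cell-count target for desk execution
#'   (1 = the full published protocol).
#' @param safety_cells Hard cap on the final phase's population size.
#' @return A [treatment_schedule()].
#' @export
preset_pemigatinib_pulse <- function(gamma = 0.9, scale = 0.1,
                                     safety_cells = 5e6 * scale) {
  stopifnot(scale > 0, scale <= 1)
  n <- function(x) max(2L, as.integer(round(x * scale)))
  base <- sim_params(
    k_init = c(10, 10),
    s_minus_minus = 0, s_minus_plus = 0.15,
    s_plus_minus = 0.15, s_plus_plus = 0.8,
    lambda_base = 0.5, mu = 1 / 2.5,
    coseg = coseg_params(gamma = gamma),
    target_cells = n(5000))
  phases <- list(
    phase_spec("burn_in", target_cells = n(5000), bin_width = 5),
    phase_spec("treatment_1", s_plus_plus = -0.1, s_plus_minus = -0.1,
               target_cells = n(1e5), bin_width = 1),
    phase_spec("holiday", lambda_base = 0.4,
               bottleneck_sample = n(25000),
               target_cells = n(1.2e6), bin_width = 1),
    phase_spec("treatment_2", s_plus_plus = -0.1, s_plus_minus = -0.1,
               bottleneck_sample = n(2e5),
               target_time = 110, target_cells = as.integer(safety_cells),
               bin_width = 1))
  treatment_schedule(base, phases,
                     meta = list(preset = "pemigatinib_pulse",
                                 death_mean = 2.5, scale = scale,
                                 targeted_species = 1))
}

#' Base parameters of the enhancer-only ecDNA sweep
#'
#' Species 1 is an oncogene-bearing ecDNA (selected on its own,
#' `s_plus_minus = 0.2`); species 2 carries only enhancer elements and
#' confers no advantage alone (`s_minus_plus = 0`) but boosts fitness when
#' co-occurring with the oncogene (`s_plus_plus`, swept). No death,
#' `lambda_base = 0.5`, founders at 5 copies each.
#'
#' @param s_plus_plus Co-selection coefficient.
#' @param gamma Co-segregation coefficient.
#' @param target_cells Population size per simulation.
#' @return A [sim_params()] object.
#' @export
preset_enhancer_only <- function(s_plus_plus = 0, gamma = 0,
                                 target_cells = 10000) {
  sim_params(
    k_init = c(5, 5),
    s_minus_minus = 0, s_minus_plus = 0, s_plus_minus = 0.2,
    s_plus_plus = s_plus_plus,
    lambda_base = 0.5, mu = 0,
    coseg = coseg_params(gamma = gamma),
    target_cells = target_cells)
}

#' Replicated parameter sweeps over (gamma, co-selection)
#'
#' For each grid point, runs independent replicate simulations from modified
#' copies of `base` and aggregates the population summaries.
#'
#' @param base A [sim_params()] template.
#' @param grid A data frame of parameter columns to override per point; any
#'   of `gamma`, `s_plus_plus`, `s_plus_minus`, `s_minus_plus`. An empty grid
#'   yields an empty table.
#' @param replicates Replicate simulations per grid point.
#' @param target_cells Optional stop-size override.
#' @param m Co-occurrence threshold passed to [summarize_population()].
#' @param transform Correlation transform passed to [summarize_population()].
#' @param seed Optional integer seed.
#' @return A tibble: the grid columns plus `replicate` and the columns of
#'   [summarize_population()].
#' @examples
#' \donttest{
#' grid <- tidyr::expand_grid(gamma = c(0, 1), s_plus_plus = c(0, 1))
#' sweep_grid(preset_enhancer_only(target_cells = 2000), grid,
#'            replicates = 2, seed = 1)
#' }
#' @export
sweep_grid <- function(base, grid, replicates = 10, target_cells = NULL,
                       m = 1, transform = "raw", seed = NULL) {
  stopifnot(inherits(base, "sim_params"), is.data.frame(grid))
  if (nrow(grid) == 0) return(tibble::tibble())
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      params <- base
      for (col in names(grid)) {
        if (col == "gamma") params$coseg$gamma <- grid$gamma[g]
        else params[[col]] <- grid[[col]][g]
      }
      if (!is.null(target_cells)) params$target_cells <- target_cells
      purrr::map_dfr(seq_len(replicates), function(r) {
        sim <- simulate_population(params)
        dplyr::bind_cols(
          grid[g, , drop = FALSE],
          tibble::tibble(replicate = r),
          summarize_population(sim$leaves, m = m, transform = transform))
      })
    })
  })
}
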