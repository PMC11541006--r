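#' Plot an ABC posterior
#'
#' Weighted histograms of the final-generation particles, one facet per
#' inferred parameter, with the weighted posterior mean marked.
#'
#' @param object An `ecdna_abc` fit.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecdna_abc
#' @export
autoplot.ecdna_abc <- function(object, bins = 20, ...) {
  part <- object$particles
  pars <- setdiff(names(part), c("weight", "distance", "generation"))
  long <- tidyr::pivot_longer(part[, c(pars, "weight")],
                              dplyr::all_of(pars),
                              names_to = "parameter")
  means <- long %>%
    dplyr::group_by(.data$parameter) %>%
    dplyr::summarise(mean = weighted.mean(.data$value, .data$weight),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$value,
                                     weight = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean),
                        colour = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior mass",
                  title = paste0("ABC-SMC posterior",
                                 if (nzchar(object$obs$label))
                                   paste0(" (", object$obs$label, ")")))
}

#' Plot a treatment-schedule trajectory
#'
#' Time-binned mean copy number per ecDNA species across the phases of a
#' schedule, with phase boundaries marked.
#'
#' @param object An `ecdna_trajectory` from [run_schedule()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecdna_trajectory
#' @export
autoplot.ecdna_trajectory <- function(object, ...) {
  long <- object$bins %>%
    tidyr::pivot_longer(c("mean_k1", "mean_k2"),
                        names_to = "species", values_to = "mean_cn") %>%
    dplyr::mutate(species = ifelse(.data$species == "mean_k1",
                                   "species 1", "species 2"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_mid, .data$mean_cn,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$phase_ends,
                        ggplot2::aes(xintercept = .data$end_time),
                        linetype = 3, colour = "grey50") +
    ggplot2::labs(x = "time", y = "mean copy number", colour = NULL)
}

#' Heat map of a (gamma, co-selection) sweep
#'
#' Averages a chosen summary statistic over replicates at each grid point of
#' a [sweep_grid()] result and draws the grid as a tile map.
#'
#' @param sweep A tibble from [sweep_grid()] with `gamma` and `s_plus_plus`
#'   columns.
#' @param stat Which summary to show, e.g. `"correlation"`,
#'   `"co_occurrence"`, `"mix"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, stat = "correlation") {
  stopifnot(all(c("gamma", "s_plus_plus", stat) %in% names(sweep)))
  agg <- sweep %>%
    dplyr::group_by(.data$gamma, .data$s_plus_plus) %>%
    dplyr::summarise(value = mean(.data[[stat]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(factor(.data$gamma),
                                    factor(.data$s_plus_plus),
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = stat) +
    ggplot2::labs(x = "co-segregation (gamma)", y = "co-selection (s++)")
}
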