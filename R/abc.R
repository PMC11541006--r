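#' Observed co-assortment summary statistics
#'
#' The inference targets: the co-occurrence `C_obs` (fraction of cells with
#' more than `m` copies of each amplified gene) and the Pearson correlation
#' `rho_obs` of log-transformed single-cell copy numbers.
#'
#' @param c_obs Co-occurrence in `[0, 1]`.
#' @param rho_obs Copy-number correlation in `[-1, 1]`.
#' @param label Optional text label (e.g. a cell-line name).
#' @return An object of class `observed_stats`.
#' @examples
#' observed_stats(0.99, 0.46, "SNU16m1")
#' @export
observed_stats <- function(c_obs, rho_obs, label = "") {
  if (!is.numeric(c_obs) || c_obs < 0 || c_obs > 1) {
    stop("`c_obs` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rho_obs) || rho_obs < -1 || rho_obs > 1) {
    stop("`rho_obs` must be in [-1, 1]", call. = FALSE)
  }
  structure(list(c_obs = c_obs, rho_obs = rho_obs, label = label),
            class = "observed_stats")
}

#' Published single-cell co-assortment targets for three ecDNA cell lines
#'
#' The co-occurrence / correlation pairs measured from single-cell ATAC
#' copy-number profiles of SNU16m1 (FGFR2 + MYC ecDNA), TR14 (MYCN + CDK4 +
#' MDM2 ecDNA) and GBM39-KT (EGFR + KIT ecDNA), used as ABC inference targets.
#'
#' @return A tibble with columns `label`, `c_obs`, `rho_obs`.
#' @examples
#' cell_line_targets()
#' @export
cell_line_targets <- function() {
  tibble::tibble(
    label = c("SNU16m1", "TR14", "GBM39-KT"),
    c_obs = c(0.99, 0.96, 0.67),
    rho_obs = c(0.46, 0.26, 0.36))
}

#' Configuration of the ABC-SMC inference
#'
#' Priors are `s_indiv ~ Unif(0, 1)` (a single tied coefficient applied to
#' both single-species classes), `s_plus_plus ~ Unif(0, 2)` and
#' `gamma ~ Unif(0, 1)`. Each proposed parameter set is scored by simulating
#' a population (`lambda_base = 0.5`, no death, `s_minus_minus = 0`) to
#' `sim_cells` cells and comparing summaries at threshold `m_abc` with the
#' log transform.
#'
#' @param epsilon_target Final tolerance on the distance
#'   `D = |C_obs - C_0| + |rho_obs - rho_0|`.
#' @param sim_cells Population size per simulated dataset. The desk default
#'   (20,000) trades fidelity for speed; raise it for sharper posteriors.
#' @param k_init Founder copy number (applied to both species).
#' @param n_particles Particles per SMC generation.
#' @param max_generations Budget on SMC generations.
#' @param max_attempts_factor Per-generation proposal budget, as a multiple
#'   of `n_particles`.
#' @param m_abc Co-occurrence threshold (strict `>`; the inference convention
#'   is more than 2 copies of each species).
#' @param tie_indiv Keep the two single-species selection coefficients tied
#'   (the default); untied adds a fourth inferred parameter.
#' @param coseg_model Segregation rule used inside the simulator.
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(epsilon_target = 0.05, sim_cells = 20000,
                       k_init = 5, n_particles = 200,
                       max_generations = 15, max_attempts_factor = 50,
                       m_abc = 2, tie_indiv = TRUE,
                       coseg_model = "element_level") {
  stopifnot(epsilon_target > 0, sim_cells >= 100, n_particles >= 10,
            k_init >= 1, max_generations >= 1, m_abc >= 0)
  structure(
    list(epsilon_target = epsilon_target, sim_cells = sim_cells,
         k_init = k_init, n_particles = n_particles,
         max_generations = max_generations,
         max_attempts_factor = max_attempts_factor,
         m_abc = m_abc, tie_indiv = tie_indiv, coseg_model = coseg_model),
    class = "abc_config")
}

#' ABC distance between observed and simulated summaries
#'
#' `D = |C_obs - C_0| + |rho_obs - rho_0|`. A simulation whose correlation is
#' undefined (constant copy numbers) receives an infinite distance and is
#' always rejected.
#'
#' @param obs An [observed_stats()] object.
#' @param sim A one-row summary as returned by [summarize_population()].
#' @return A non-negative scalar (possibly `Inf`).
#' @examples
#' obs <- observed_stats(0.99, 0.46)
#' sim <- tibble::tibble(co_occurrence = 0.96, correlation = 0.44,
#'                       correlation_defined = TRUE)
#' abc_distance(obs, sim) # 0.05
#' @export
abc_distance <- function(obs, sim) {
  stopifnot(inherits(obs, "observed_stats"))
  if (!isTRUE(sim$correlation_defined[1]) || is.na(sim$correlation[1])) {
    return(Inf)
  }
  abs(obs$c_obs - sim$co_occurrence[1]) + abs(obs$rho_obs - sim$correlation[1])
}

#' Draw parameter sets from the prior
#'
#' @param config An [abc_config()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `s_indiv`, `s_plus_plus`, `gamma` (and
#'   `s_indiv2` when the single-species coefficients are untied).
#' @export
sample_prior <- function(config, n = 1, seed = NULL) {
  stopifnot(inherits(config, "abc_config"))
  with_seed(seed, {
    out <- tibble::tibble(
      s_indiv = runif(n, 0, 1),
      s_plus_plus = runif(n, 0, 2),
      gamma = runif(n, 0, 1))
    if (!config$tie_indiv) out$s_indiv2 <- runif(n, 0, 1)
    out
  })
}

prior_bounds <- function(config) {
  b <- list(s_indiv = c(0, 1), s_plus_plus = c(0, 2), gamma = c(0, 1))
  if (!config$tie_indiv) b$s_indiv2 <- c(0, 1)
  b
}

# Simulate one dataset at theta and return its (C, rho) summary under the
# ABC conventions (threshold m_abc, log transform). theta is a named list/row.
abc_simulate <- function(theta, config) {
  s2 <- if (config$tie_indiv) theta$s_indiv else theta$s_indiv2
  params <- sim_params(
    k_init = c(config$k_init, config$k_init),
    s_minus_minus = 0,
    s_plus_minus = theta$s_indiv,
    s_minus_plus = s2,
    s_plus_plus = theta$s_plus_plus,
    lambda_base = 0.5, mu = 0,
    coseg = coseg_params(gamma = theta$gamma, model = config$coseg_model),
    target_cells = config$sim_cells)
  sim <- simulate_population(params)
  summarize_population(sim$leaves, m = config$m_abc, transform = "log")
}

#' Infer selection, co-selection and co-segregation by ABC-SMC
#'
#' Sequential Monte Carlo ABC. Generation 1 samples from the prior; later
#' generations resample accepted particles by weight, perturb them with a
#' component-wise Gaussian kernel (variance = 2x the weighted sample variance
#' of the previous generation, proposals outside the prior redrawn), simulate
#' a population at the proposal, and accept when the distance
#' `D = |C_obs - C_0| + |rho_obs - rho_0|` is at most the generation
#' tolerance. Tolerances follow the adaptive median schedule and the run
#' stops after a generation at `epsilon_target` completes, or when the
#' generation/proposal budget is exhausted (flagged, not an error). A
#' generation with zero acceptances raises a tolerance-stall error with
#' diagnostics.
#'
#' @param obs An [observed_stats()] object.
#' @param config An [abc_config()] object.
#' @param seed Optional integer seed for the whole run.
#' @param verbose Print per-generation progress.
#' @return An object of class `ecdna_abc`: list with `particles` (tibble of
#'   the final generation: parameters, `weight`, `distance`), `history`
#'   (all generations), `epsilon_achieved`, `converged`, `obs`, `config`.
#' @examples
#' \donttest{
#' obs <- observed_stats(0.96, 0.26, "TR14")
#' fit <- run_abc_smc(obs, abc_config(sim_cells = 2000, n_particles = 50),
#'                    seed = 1)
#' credible_interval(fit)
#' }
#' @export
run_abc_smc <- function(obs, config = abc_config(), seed = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(obs, "observed_stats"), inherits(config, "abc_config"))
  with_seed(seed, run_abc_smc_impl(obs, config, verbose))
}

run_abc_smc_impl <- function(obs, config, verbose) {
  n <- config$n_particles
  bounds <- prior_bounds(config)
  pars <- names(bounds)
  max_attempts <- config$max_attempts_factor * n

  draw_gen <- function(prev, eps) {
    acc <- vector("list", n)
    dist <- numeric(n)
    n_acc <- 0L
    attempts <- 0L
    while (n_acc < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      if (is.null(prev)) {
        theta <- as.list(sample_prior(config, 1))
      } else {
        theta <- propose_particle(prev, bounds, pars)
      }
      smry <- abc_simulate(theta, config)
      d <- abc_distance(obs, smry)
      if (d <= eps) {
        n_acc <- n_acc + 1L
        acc[[n_acc]] <- theta
        dist[n_acc] <- d
      }
    }
    list(theta = acc[seq_len(n_acc)], distance = dist[seq_len(n_acc)],
         attempts = attempts)
  }

  history <- list()
  prev <- NULL
  eps <- Inf
  converged <- FALSE
  for (gen in seq_len(config$max_generations)) {
    res <- draw_gen(prev, eps)
    n_acc <- length(res$theta)
    if (n_acc == 0) {
      stop("ABC-SMC stalled: no acceptances in generation ", gen,
           " at tolerance ", format(eps, digits = 4), " after ",
           res$attempts, " proposals (target ", config$epsilon_target, ")",
           call. = FALSE)
    }
    part <- dplyr::bind_rows(lapply(res$theta, tibble::as_tibble))
    part$distance <- res$distance
    part$weight <- compute_weights(part, prev, bounds, pars)
    part$generation <- gen
    history[[gen]] <- part
    if (verbose) {
      message(sprintf(
        "generation %d: eps = %.4f, accepted %d/%d proposals, median D = %.4f",
        gen, eps, n_acc, res$attempts, median(part$distance)))
    }
    if (is.finite(eps) && eps <= config$epsilon_target && n_acc == n) {
      converged <- TRUE
      break
    }
    if (n_acc < n) break  # proposal budget exhausted mid-generation
    prev <- part
    eps_next <- median(part$distance)
    if (is.finite(eps) && eps_next >= eps) eps_next <- 0.95 * eps
    eps <- max(eps_next, config$epsilon_target)
  }
  final <- history[[length(history)]]
  structure(
    list(particles = final,
         history = dplyr::bind_rows(history),
         epsilon_achieved = max(final$distance),
         converged = converged,
         n_generations = length(history),
         obs = obs, config = config),
    class = "ecdna_abc")
}

propose_particle <- function(prev, bounds, pars) {
  repeat {
    i <- sample.int(nrow(prev), 1, prob = prev$weight)
    theta <- list()
    ok <- TRUE
    for (p in pars) {
      sdv <- sqrt(2 * weighted_var(prev[[p]], prev$weight))
      if (!is.finite(sdv) || sdv == 0) sdv <- 1e-6
      val <- prev[[p]][i] + rnorm(1, 0, sdv)
      if (val < bounds[[p]][1] || val > bounds[[p]][2]) { ok <- FALSE; break }
      theta[[p]] <- val
    }
    if (ok) return(theta)
  }
}

weighted_var <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sum(w * (x - m)^2)
}

compute_weights <- function(part, prev, bounds, pars) {
  if (is.null(prev)) return(rep(1 / nrow(part), nrow(part)))
  sdv <- vapply(pars, function(p) {
    s <- sqrt(2 * weighted_var(prev[[p]], prev$weight))
    if (!is.finite(s) || s == 0) 1e-6 else s
  }, numeric(1))
  w <- vapply(seq_len(nrow(part)), function(j) {
    dens <- rep(1, nrow(prev))
    for (p in pars) {
      dens <- dens * stats::dnorm(part[[p]][j], prev[[p]], sdv[[p]])
    }
    1 / sum(prev$weight * dens)  # flat prior: numerator constant
  }, numeric(1))
  w / sum(w)
}

#' Weighted credible intervals of an ABC posterior
#'
#' Central weighted-quantile interval per parameter at the requested level.
#'
#' @param posterior An `ecdna_abc` object (or its particles tibble with a
#'   `weight` column).
#' @param level Credibility level (default 0.95).
#' @return A tibble: `parameter`, `mean`, `lower`, `upper`, `level`.
#' @export
credible_interval <- function(posterior, level = 0.95) {
  part <- if (inherits(posterior, "ecdna_abc")) posterior$particles
          else posterior
  stopifnot(is.data.frame(part), "weight" %in% names(part))
  pars <- setdiff(names(part), c("weight", "distance", "generation"))
  if (nrow(part) < 2) warning("single particle: degenerate interval")
  alpha <- (1 - level) / 2
  purrr::map_dfr(pars, function(p) {
    tibble::tibble(
      parameter = p,
      mean = weighted.mean(part[[p]], part$weight),
      lower = weighted_quantile(part[[p]], part$weight, alpha),
      upper = weighted_quantile(part[[p]], part$weight, 1 - alpha),
      level = level)
  })
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' @export
print.ecdna_abc <- function(x, ...) {
  cat("<ecdna_abc> ", x$n_generations, " generations, ",
      nrow(x$particles), " particles, achieved tolerance ",
      format(x$epsilon_achieved, digits = 4),
      if (x$converged) "" else " (budget exhausted before target)",
      "\n", sep = "")
  print(credible_interval(x))
  invisible(x)
}

#' @method tidy ecdna_abc
#' @export
tidy.ecdna_abc <- function(x, ...) x$particles

#' @method glance ecdna_abc
#' @export
glance.ecdna_abc <- function(x, ...) {
  tibble::tibble(
    label = x$obs$label,
    c_obs = x$obs$c_obs, rho_obs = x$obs$rho_obs,
    n_particles = nrow(x$particles),
    n_generations = x$n_generations,
    epsilon_achieved = x$epsilon_achieved,
    converged = x$converged)
}

#' Re-simulate populations at posterior draws
#'
#' Posterior predictive check: draws `n_draws` particles by weight,
#' re-simulates a population at each and returns the achieved summaries
#' next to the observed targets.
#'
#' @param fit An `ecdna_abc` object.
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed.
#' @return A tibble with one row per draw: the parameters, `co_occurrence`,
#'   `correlation`, `abs_err_c`, `abs_err_rho`.
#' @export
posterior_predictive <- function(fit, n_draws = 20, seed = NULL) {
  stopifnot(inherits(fit, "ecdna_abc"))
  with_seed(seed, {
    part <- fit$particles
    idx <- sample.int(nrow(part), n_draws, replace = TRUE,
                      prob = part$weight)
    purrr::map_dfr(idx, function(i) {
      theta <- as.list(part[i, setdiff(names(part),
                                       c("weight", "distance", "generation"))])
      smry <- abc_simulate(theta, fit$config)
      tibble::tibble(
        !!!theta,
        co_occurrence = smry$co_occurrence,
        correlation = smry$correlation,
        abs_err_c = abs(smry$co_occurrence - fit$obs$c_obs),
        abs_err_rho = abs(smry$correlation - fit$obs$rho_obs))
    })
  })
}
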