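test_that("the ABC distance is the printed L1 distance on (C, rho)", {
  obs <- observed_stats(0.99, 0.46)
  same <- tibble::tibble(co_occurrence = 0.99, correlation = 0.46,
                         correlation_defined = TRUE)
  expect_equal(abc_distance(obs, same), 0)
  sim <- tibble::tibble(co_occurrence = 0.96, correlation = 0.44,
                        correlation_defined = TRUE)
  expect_equal(abc_distance(obs, sim), 0.05)
  # symmetric in the sign of the differences
  sim2 <- tibble::tibble(co_occurrence = 1.00, correlation = 0.48,
                         correlation_defined = TRUE)
  expect_equal(abc_distance(observed_stats(0.98, 0.46), sim2), 0.04)
  undef <- tibble::tibble(co_occurrence = 1, correlation = NA_real_,
                          correlation_defined = FALSE)
  expect_identical(abc_distance(obs, undef), Inf)
  expect_error(observed_stats(1.2, 0), "c_obs")
})

test_that("prior draws follow Unif(0,1) x Unif(0,2) x Unif(0,1)", {
  cfg <- abc_config(sim_cells = 1000)
  th <- sample_prior(cfg, n = 1e5, seed = 1)
  expect_lt(abs(mean(th$s_plus_plus) - 1), 0.01)
  expect_true(all(th$gamma >= 0 & th$gamma <= 1))
  expect_true(all(th$s_indiv >= 0 & th$s_indiv <= 1))
  expect_true(all(th$s_plus_plus >= 0 & th$s_plus_plus <= 2))
  ks <- suppressWarnings(
    stats::ks.test(sample_prior(cfg, 1e4, seed = 2)$s_indiv, "punif"))
  expect_gt(ks$p.value, 0.01)
  # untied option adds the fourth coefficient
  th4 <- sample_prior(abc_config(sim_cells = 1000, tie_indiv = FALSE), 10,
                      seed = 3)
  expect_true("s_indiv2" %in% names(th4))
})

test_that("weighted credible intervals match the quantile oracle", {
  part <- tibble::tibble(gamma = seq(0.1, 1, by = 0.1),
                         weight = rep(0.1, 10),
                         distance = 0, generation = 1L)
  ci <- credible_interval(part, level = 0.95)
  # oracle: smallest x with cumulative weight >= prob
  expect_equal(ci$lower, 0.1)
  expect_equal(ci$upper, 1.0)
  expect_equal(ci$mean, 0.55)

  same <- tibble::tibble(gamma = rep(0.4, 5), weight = rep(0.2, 5),
                         distance = 0, generation = 1L)
  ci2 <- credible_interval(same)
  expect_equal(ci2$upper - ci2$lower, 0)

  conc <- tibble::tibble(gamma = c(0.2, 0.9),
                         weight = c(0.01, 0.99),
                         distance = 0, generation = 1L)
  ci3 <- credible_interval(conc)
  # oracle: the light (1%) tail sits below the 2.5% quantile, so the whole
  # interval collapses onto the dominant particle
  expect_equal(ci3$upper, 0.9)
  expect_equal(ci3$lower, 0.9)
  expect_gt(ci3$mean, 0.88)
})

test_that("ABC-SMC accepts only within tolerance and is seed-reproducible", {
  obs <- gen_observed_stats(list(s_indiv = 0.2, s_plus_plus = 1, gamma = 0.8),
                            sim_cells = 5000, seed = 31)$obs
  cfg <- abc_config(sim_cells = 5000, n_particles = 40,
                    epsilon_target = 0.12, max_generations = 6,
                    max_attempts_factor = 30)
  fit <- run_abc_smc(obs, cfg, seed = 32)
  expect_s3_class(fit, "ecdna_abc")
  expect_true(all(fit$particles$distance <= fit$epsilon_achieved))
  expect_equal(sum(fit$particles$weight), 1)
  if (fit$converged) expect_lte(fit$epsilon_achieved, 0.12)
  fit2 <- run_abc_smc(obs, cfg, seed = 32)
  expect_identical(fit$particles, fit2$particles)
  g <- glance(fit)
  expect_equal(g$n_particles, nrow(fit$particles))
  expect_identical(tidy(fit), fit$particles)
})

test_that("posterior predictive re-simulation tracks the fitted target", {
  obs <- gen_observed_stats(list(s_indiv = 0.2, s_plus_plus = 1, gamma = 0.8),
                            sim_cells = 5000, seed = 41)$obs
  cfg <- abc_config(sim_cells = 5000, n_particles = 40,
                    epsilon_target = 0.1, max_generations = 7,
                    max_attempts_factor = 30)
  fit <- run_abc_smc(obs, cfg, seed = 42)
  pp <- posterior_predictive(fit, n_draws = 10, seed = 43)
  expect_equal(nrow(pp), 10)
  # re-simulated summaries stay near the target when tolerance was reached
  if (fit$converged) {
    expect_lt(mean(pp$abs_err_c) + mean(pp$abs_err_rho), 3 * 0.1)
  }
})

test_that("an infeasible target does not silently succeed", {
  obs <- observed_stats(0, 0, "degenerate")
  cfg <- abc_config(sim_cells = 2000, n_particles = 20,
                    max_generations = 4, max_attempts_factor = 10)
  out <- tryCatch(run_abc_smc(obs, cfg, seed = 5), error = identity)
  if (inherits(out, "error")) {
    expect_match(conditionMessage(out), "stalled")
  } else {
    expect_false(out$converged)
  }
})

test_that("credible intervals widen for co-selection, not co-segregation, at high founder copies", {
  gen <- gen_observed_stats(list(s_indiv = 0.2, s_plus_plus = 1, gamma = 0.5),
                            sim_cells = 10000, k_init = 5, seed = 51)
  widths <- purrr::map_dfr(c(5, 20), function(k) {
    cfg <- abc_config(sim_cells = 10000, k_init = k, n_particles = 50,
                      epsilon_target = 0.1, max_generations = 6,
                      max_attempts_factor = 25)
    fit <- run_abc_smc(gen$obs, cfg, seed = 52)
    ci <- credible_interval(fit)
    tibble::tibble(k_init = k,
                   gamma_w = ci$upper[ci$parameter == "gamma"] -
                     ci$lower[ci$parameter == "gamma"],
                   spp_w = ci$upper[ci$parameter == "s_plus_plus"] -
                     ci$lower[ci$parameter == "s_plus_plus"])
  })
  expect_lt(widths$gamma_w[2], 2 * widths$gamma_w[1])
  expect_gt(widths$gamma_w[2], widths$gamma_w[1] / 2)
  expect_gt(widths$spp_w[2], widths$spp_w[1])
})
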