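test_that("birth rate follows lambda_base * (1 + s) by presence class", {
  p <- sim_params(s_minus_minus = 0, s_plus_minus = 0.2, s_minus_plus = 0.3,
                  s_plus_plus = 1, lambda_base = 0.5, target_cells = 10)
  expect_equal(compute_birth_rate(c(0, 0), p), 0.5)
  expect_equal(compute_birth_rate(c(3, 0), p), 0.6)
  expect_equal(compute_birth_rate(c(0, 2), p), 0.65)
  expect_equal(compute_birth_rate(c(1, 1), p), 1.0)
  expect_error(sim_params(s_minus_minus = -1, target_cells = 10), "positive")
})

test_that("stop conditions and determinism behave as specified", {
  p <- sim_params(k_init = c(5, 5), target_cells = 1)
  sim <- simulate_population(p, seed = 1)
  expect_equal(sim$n_cells, 1)
  expect_equal(c(sim$leaves$k1, sim$leaves$k2), c(5, 5))

  p2 <- sim_params(k_init = c(5, 5), s_plus_plus = 0.5,
                   coseg = coseg_params(gamma = 0.5), target_cells = 500)
  s1 <- simulate_population(p2, seed = 7)
  s2 <- simulate_population(p2, seed = 7)
  expect_identical(s1$leaves, s2$leaves)
  expect_identical(s1$final_time, s2$final_time)
  expect_equal(s1$n_cells, 500)

  # time stop: clock halts exactly at the target and cells mid-waiting-time
  # count as leaves
  p3 <- sim_params(k_init = c(5, 5), target_time = 3)
  s3 <- simulate_population(p3, seed = 8)
  expect_equal(s3$final_time, 3)
  expect_gte(s3$n_cells, 1)

  # supercritical growth always reaches the target without death
  for (seed in 1:5) {
    s <- simulate_population(
      sim_params(k_init = c(2, 2), target_cells = 300), seed = seed)
    expect_equal(s$n_cells, 300)
  }
})

test_that("heavy death yields an explicit extinct result, not an error", {
  p <- sim_params(k_init = c(5, 5), mu = 10, target_cells = 1e4)
  extinct_seen <- FALSE
  for (seed in 1:10) {
    s <- simulate_population(p, seed = seed)
    if (s$extinct) {
      extinct_seen <- TRUE
      expect_equal(nrow(s$leaves), 0)
    }
  }
  expect_true(extinct_seen)
})

test_that("neutral segregation preserves mean copy number (martingale)", {
  means <- t(vapply(1:50, function(seed) {
    s <- simulate_population(
      sim_params(k_init = c(5, 5), target_cells = 1000), seed = seed)
    c(mean(s$leaves$k1), mean(s$leaves$k2))
  }, numeric(2)))
  for (j in 1:2) {
    se <- sd(means[, j]) / sqrt(nrow(means))
    expect_lt(abs(mean(means[, j]) - 5), 3 * se)
  }
})

test_that("population summaries implement the printed formulas", {
  leaves <- tibble::tibble(k1 = c(2, 0, 1), k2 = c(3, 5, 1))
  sm <- summarize_population(leaves, m = 1)
  expect_equal(sm$co_occurrence, 1 / 3)

  perfect <- tibble::tibble(k1 = c(1, 2, 5, 9), k2 = c(2, 4, 10, 18))
  expect_equal(summarize_population(perfect, m = 1)$correlation, 1)

  const <- tibble::tibble(k1 = c(4, 4), k2 = c(4, 4))
  smc <- summarize_population(const, m = 1)
  expect_false(smc$correlation_defined)
  expect_true(is.na(smc$correlation))
  expect_equal(smc$co_occurrence, 1)

  expect_error(summarize_population(leaves[0, ]), "empty")

  fr <- subpopulation_fractions(
    tibble::tibble(k1 = c(1, 2, 0, 0), k2 = c(1, 0, 0, 3)))
  expect_equal(unlist(fr), c(pure = 0.5, mix = 0.25, free = 0.25))
  expect_equal(
    subpopulation_fractions(tibble::tibble(k1 = c(0, 0), k2 = c(0, 0)))$free, 1)
  expect_equal(
    subpopulation_fractions(tibble::tibble(k1 = 1:3, k2 = 3:1))$mix, 1)
  # fractions always sum to one
  s <- simulate_population(sim_params(k_init = c(2, 2), target_cells = 400),
                           seed = 3)
  fr2 <- subpopulation_fractions(s$leaves)
  expect_equal(fr2$pure + fr2$mix + fr2$free, 1)
})

test_that("log transform is used for the observation-facing correlation", {
  leaves <- tibble::tibble(k1 = c(0, 1, 5, 50), k2 = c(1, 2, 4, 60))
  raw <- summarize_population(leaves, transform = "raw")$correlation
  lg <- summarize_population(leaves, transform = "log")$correlation
  expect_equal(lg, cor(log1p(leaves$k1), log1p(leaves$k2)))
  expect_false(isTRUE(all.equal(raw, lg)))
})

test_that("recorded lineages yield a valid phylogeny over surviving cells", {
  p <- sim_params(k_init = c(5, 5), mu = 0.2, target_cells = 40)
  sim <- NULL
  for (seed in 21:40) {
    cand <- simulate_population(p, seed = seed, record_tree = TRUE)
    if (!cand$extinct) { sim <- cand; break }
  }
  tree <- sim_tree(sim)
  expect_s3_class(tree, "phylo")
  expect_equal(ape::Ntip(tree), sim$n_cells)
  expect_true(all(tree$edge.length >= 0))
  # leaf labels carry copy states consistent with the leaf multiset
  states <- sub("^cell[0-9]+_", "", tree$tip.label)
  leafst <- sort(paste0(sim$leaves$k1, "_", sim$leaves$k2))
  expect_equal(sort(states), leafst)
  expect_error(sim_tree(simulate_population(p, seed = seed)), "record_tree")
})

test_that("gamma raises correlation and co-selection raises co-occurrence (cell-level rule)", {
  withr::local_seed(202)
  reps <- 20
  res <- purrr::map_dfr(c(0, 1), function(g) {
    purrr::map_dfr(c(0, 1), function(spp) {
      purrr::map_dfr(seq_len(reps), function(r) {
        s <- simulate_population(sim_params(
          k_init = c(5, 5), s_plus_minus = 0.2, s_minus_plus = 0.2,
          s_plus_plus = spp,
          coseg = coseg_params(gamma = g, model = "cell_level"),
          target_cells = 10000))
        dplyr::bind_cols(tibble::tibble(g = g, spp = spp, rep = r),
                         summarize_population(s$leaves, m = 1))
      })
    })
  })
  for (spp in c(0, 1)) {
    hi <- res$correlation[res$g == 1 & res$spp == spp]
    lo <- res$correlation[res$g == 0 & res$spp == spp]
    expect_lt(stats::t.test(hi, lo, alternative = "greater")$p.value, 0.05)
  }
  for (g in c(0, 1)) {
    hi <- res$co_occurrence[res$spp == 1 & res$g == g]
    lo <- res$co_occurrence[res$spp == 0 & res$g == g]
    expect_lt(stats::t.test(hi, lo, alternative = "greater")$p.value, 0.05)
  }
})

test_that("leaves export as the documented TSV", {
  sim <- simulate_population(sim_params(k_init = c(3, 3), target_cells = 50),
                             seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_leaves_tsv(sim, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("cell_id", "k1", "k2"))
  expect_equal(back$k1, sim$leaves$k1)
})
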