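test_that("all rules conserve copies and reject invalid parameters", {
  parents <- list(c(0, 0), c(1, 7), c(10, 10), c(3, 50), c(120, 4))
  models <- list(
    coseg_params(gamma = 0.7),
    coseg_params(gamma = 0.3, model = "cell_level"),
    coseg_params(model = "fraction_coupled", coupled_fraction = 0.4),
    coseg_params(gamma = 1, anchor_species = 2))
  for (p in parents) {
    for (m in models) {
      d <- segregate_divisions(p, m, n = 200, seed = 42)
      tot <- d$n_daughter1 + d$n_daughter2
      expect_equal(tot[d$species == 1], rep(2 * p[1], 200))
      expect_equal(tot[d$species == 2], rep(2 * p[2], 200))
      expect_true(all(d$n_daughter1 >= 0 & d$n_daughter2 >= 0))
    }
  }
  expect_error(coseg_params(gamma = 1.2), "gamma")
  expect_error(coseg_params(model = "fraction_coupled",
                            coupled_fraction = -0.1), "coupled_fraction")
  expect_error(segregate_divisions(c(-1, 5), coseg_params()), "non-negative")
})

test_that("element-level rule follows the proportional coupling equations", {
  # empty parent: both daughters empty
  d0 <- divisions_wide(c(0, 0), coseg_params(gamma = 1), n = 10, seed = 1)
  expect_true(all(d0$n1_d1 == 0) && all(d0$n2_d1 == 0))

  # gamma = 1, equal parental copies: coupled part is exactly the anchor
  # split (n2 = gamma * 2N2 * n1 / (2N1) = n1), remainder 0
  d <- segregate_divisions(c(10, 10), coseg_params(gamma = 1), n = 500,
                           seed = 2)
  n1 <- d$n_daughter1[d$species == 1]
  n2 <- d$n_daughter1[d$species == 2]
  expect_equal(n2, n1)
  coup <- d$coupled_part1[d$species == 2]
  expect_equal(coup, as.numeric(n1))
  expect_true(all(is.na(d$coupled_part1[d$species == 1])))

  # conditioned check at n1 = 14 of 20: n2 daughters must be (14, 6)
  sub <- d[d$division %in% d$division[d$species == 1 & d$n_daughter1 == 14], ]
  if (nrow(sub) > 0) {
    expect_true(all(sub$n_daughter1[sub$species == 2] == 14))
    expect_true(all(sub$n_daughter2[sub$species == 2] == 6))
  }

  # N1 = 0 with N2 > 0: no anchor signal, species 2 splits binomially
  dz <- divisions_wide(c(0, 40), coseg_params(gamma = 1), n = 2e4, seed = 3)
  expect_gt(binomial_gof_p(dz$n2_d1, 80), 0.01)
})

test_that("gamma = 0 element-level split is Binomial(2N, 1/2) for both species", {
  d <- divisions_wide(c(10, 10), coseg_params(gamma = 0), n = 1e5, seed = 4)
  expect_gt(binomial_gof_p(d$n1_d1, 20), 0.01)
  expect_gt(binomial_gof_p(d$n2_d1, 20), 0.01)
  # and independence: correlation compatible with zero
  expect_lt(abs(cor(d$n1_d1, d$n2_d1)), 0.02)
})

test_that("cell-level rule pairs extreme halves with probability gamma", {
  # gamma = 0.5 reproduces independent segregation
  d <- divisions_wide(c(10, 10), coseg_params(gamma = 0.5, model = "cell_level"),
                      n = 1e5, seed = 5)
  expect_gt(binomial_gof_p(d$n2_d1, 20), 0.01)
  expect_lt(abs(cor(d$n1_d1, d$n2_d1)), 0.02)

  # gamma = 1: unequal splits always go the same way
  d1 <- divisions_wide(c(10, 10), coseg_params(gamma = 1, model = "cell_level"),
                       n = 2e4, seed = 6)
  uneq <- d1$n1_d1 != 10 & d1$n2_d1 != 10
  expect_true(all(sign(d1$n1_d1[uneq] - 10) == sign(d1$n2_d1[uneq] - 10)))

  # anchor tie: species-2 outcome distribution is gamma-invariant
  t0 <- divisions_wide(c(10, 10), coseg_params(gamma = 0, model = "cell_level"),
                       n = 4e4, seed = 7)
  t1 <- divisions_wide(c(10, 10), coseg_params(gamma = 1, model = "cell_level"),
                       n = 4e4, seed = 8)
  x0 <- t0$n2_d1[t0$n1_d1 == 10]
  x1 <- t1$n2_d1[t1$n1_d1 == 10]
  expect_gt(two_sample_gof_p(x0, x1), 0.01)
})

test_that("fraction-coupled rule interpolates between independence and lockstep", {
  # phi = 0: independent binomial splits
  d <- divisions_wide(c(10, 10),
                      coseg_params(model = "fraction_coupled",
                                   coupled_fraction = 0),
                      n = 1e5, seed = 9)
  expect_gt(binomial_gof_p(d$n1_d1, 20), 0.01)
  expect_lt(abs(cor(d$n1_d1, d$n2_d1)), 0.02)

  # phi = 1: daughter proportions agree exactly up to ratio rounding
  d1 <- divisions_wide(c(50, 50),
                       coseg_params(model = "fraction_coupled",
                                    coupled_fraction = 1),
                       n = 2000, seed = 10)
  expect_true(all(abs(d1$n1_d1 / 100 - d1$n2_d1 / 100) <= 1 / 100))

  # correlation of daughter proportions increases in phi and phi = 0.5 sits
  # strictly between the endpoints
  curve <- coseg_calibration_curve(copies = 100,
                                   phi_grid = c(0, 0.25, 0.5, 0.75, 1),
                                   n_pairs = 1e4, seed = 11)
  expect_true(all(diff(curve$expected_r) > 0))
  expect_gt(curve$expected_r[3], curve$expected_r[1])
  expect_lt(curve$expected_r[3], curve$expected_r[5])
})

test_that("daughters are exchangeable and the anchor can be either species", {
  for (m in list(coseg_params(gamma = 0.6),
                 coseg_params(gamma = 0.8, model = "cell_level"),
                 coseg_params(model = "fraction_coupled",
                              coupled_fraction = 0.5))) {
    d <- divisions_wide(c(8, 30), m, n = 4e4, seed = 12)
    expect_gt(two_sample_gof_p(d$n2_d1, d$n2_d2), 0.01)
    expect_lt(abs(mean(d$n1_d1) - 8), 0.05)
  }
  # anchoring on species 2 couples species 1 to it at gamma = 1
  da <- segregate_divisions(c(10, 10),
                            coseg_params(gamma = 1, anchor_species = 2),
                            n = 500, seed = 13)
  expect_equal(da$n_daughter1[da$species == 1],
               da$n_daughter1[da$species == 2])
  expect_true(all(is.na(da$coupled_part1[da$species == 2])))
})

test_that("segregation is reproducible from a seed", {
  a <- segregate_divisions(c(10, 10), coseg_params(gamma = 0.5), n = 50,
                           seed = 99)
  b <- segregate_divisions(c(10, 10), coseg_params(gamma = 0.5), n = 50,
                           seed = 99)
  expect_identical(a, b)
})
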