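test_that("hyperbolic rate law matches its closed form and domain", {
  expect_identical(hyperbolic_rate(0, 0.035, 1), 0)
  # half-maximum at r = Q by definition of Q
  expect_equal(hyperbolic_rate(1, 0.035, 1), 0.0175)
  expect_equal(hyperbolic_rate(100, 0.035, 1), 0.035 * 100 / 101)
  # monotone non-decreasing in r, bounded by rate_max
  r <- seq(0, 1e3, length.out = 101)
  v <- hyperbolic_rate(r, 0.2, 3)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 0.2))
  expect_error(hyperbolic_rate(-1, 0.035, 1), "r must be")
  expect_error(hyperbolic_rate(1, 0.035, 0), "Q must be")
  expect_error(hyperbolic_rate(1, -0.1, 1), "rate_max")
})

test_that("parameter and state containers validate their domains", {
  p <- kinetic_params()
  expect_equal(p[["psi_max"]], 0.035)
  expect_equal(p[["lambda_T"]], 1 / 90)
  # P_lambda is an accepted alias for the conjugation penalty
  expect_equal(kinetic_params(P_lambda = 0.25)[["P_gamma"]], 0.25)
  expect_error(kinetic_params(P_gamma = 0.1, P_lambda = 0.2), "alias")
  expect_error(kinetic_params(bogus = 1), "unknown")
  expect_error(kinetic_params(P_psi = 1.5), "penalty")
  expect_error(kinetic_params(K = -1), "> 0")
  expect_error(population_state(n_D = -5), "non-negative")
  s <- population_state(r = 100, n_D = 2, n_R = 3, n_I = 7, n_P = 1e6)
  expect_equal(total_cells(s), 12)
})

test_that("full derivatives reproduce hand-evaluated special cases", {
  p <- tbl_params()
  # donor-only culture: pure logistic growth, no bilinear terms
  d <- derivatives_full(population_state(r = 100, n_D = 1e6), p)
  psi100 <- 0.035 * 100 / 101
  expect_equal(d[["n_D"]], psi100 * 1e6 * (1 - 1e6 / 3e9))
  expect_equal(d[["r"]], -3.5e-8 * psi100 * 1e6 * (1 - 1e6 / 3e9))
  expect_true(all(d[c("n_R", "n_T", "n_X", "n_N", "n_I", "n_XI", "n_P")] == 0))
  # phage at carrying capacity: production halts
  d2 <- derivatives_full(population_state(r = 100, n_I = 1e5, n_P = 4e11), p)
  expect_equal(d2[["n_P"]], 0)
  # empty culture is a fixed point
  d3 <- derivatives_full(population_state(r = 50), p)
  expect_true(all(d3 == 0))
  # infection flux appears with opposite signs in donors and newly infected
  d4 <- derivatives_full(population_state(r = 100, n_D = 1e6, n_P = 1e7), p)
  beta100 <- 3e-11 * 100 / 101
  flux <- beta100 * 1e6 * 1e7
  expect_equal(d4[["n_N"]], flux)
  expect_equal(d4[["n_D"]], psi100 * 1e6 * (1 - 1e6 / 3e9) - flux)
  expect_error(derivatives_full(c(r = NaN, n_D = 1), p), "finite")
})

test_that("reduced systems are bitwise-consistent with the full system", {
  p <- tbl_params()
  set.seed(42)
  for (i in 1:20) {
    y <- population_state(r = runif(1, 0, 100),
                          n_D = 10^runif(1, 0, 9), n_R = 10^runif(1, 0, 9),
                          n_T = 10^runif(1, 0, 8), n_X = 10^runif(1, 0, 8))
    expect_identical(derivatives_conjugation_only(y, p),
                     derivatives_full(y, p)[c("r", "n_D", "n_R", "n_T",
                                              "n_X")])
    y2 <- population_state(r = runif(1, 0, 100), n_D = 10^runif(1, 0, 9),
                           n_N = 10^runif(1, 0, 8), n_I = 10^runif(1, 0, 8),
                           n_P = 10^runif(1, 0, 11))
    expect_identical(derivatives_infection_only(y2, p),
                     derivatives_full(y2, p)[c("r", "n_D", "n_N", "n_I",
                                               "n_P")])
  }
  expect_error(
    derivatives_conjugation_only(population_state(r = 1, n_P = 1), p),
    "zero phage")
  expect_error(
    derivatives_infection_only(population_state(r = 1, n_R = 1), p),
    "zero conjugation")
})

test_that("growth-free limits conserve the paired compartment sums", {
  # no growth, no lag recovery: conjugation only swaps D->X and R->T
  p <- kinetic_params(psi_max = 0, lambda_T = 0, lambda_X = 0)
  d <- derivatives_conjugation_only(
    population_state(r = 100, n_D = 5e5, n_R = 5e5), p)
  expect_equal(d[["n_D"]], -d[["n_X"]])
  expect_equal(d[["n_R"]], -d[["n_T"]])
  gam <- 3e-10 * 100 / 101
  expect_equal(d[["n_D"]], -gam * 5e5 * 5e5)
  # no growth: infection only moves cells between compartments
  p2 <- kinetic_params(psi_max = 0)
  d2 <- derivatives_infection_only(
    population_state(r = 100, n_D = 1e6, n_N = 1e5, n_I = 1e5, n_P = 1e8),
    p2)
  expect_equal(d2[["n_D"]] + d2[["n_N"]] + d2[["n_I"]], 0)
})
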