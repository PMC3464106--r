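test_that("presets reproduce the documented inoculation densities", {
  c11 <- preset_condition("COND1", 1)
  expect_equal(unclass(c11$initial_state)[c("r", "n_D", "n_R")],
               c(r = 100, n_D = 5e5, n_R = 5e5))
  expect_equal(c11$duration, 700)
  c1k <- preset_condition("COND1", 1000)
  expect_equal(total_cells(c1k$initial_state), 1e6)
  expect_equal(c1k$initial_state[["n_R"]] / c1k$initial_state[["n_D"]], 1000)
  # 5 uL of a 1e11/mL phage stock into 50 mL
  expect_equal(preset_condition("COND2A", 1)$initial_state[["n_P"]], 1e7)
  expect_equal(preset_condition("COND2A", 0.1)$initial_state[["n_D"]], 3e6)
  expect_equal(preset_condition("COND2B", 1)$initial_state[["n_P"]], 1e8)
  expect_equal(preset_condition("COND2B", 1)$initial_state[["n_D"]], 3e6)
  # uniformly diluted saturated pre-infected culture keeps n_P/n_I = K_P/K
  c2c <- preset_condition("COND2C", 0.1)
  expect_equal(c2c$initial_state[["n_P"]] / c2c$initial_state[["n_I"]],
               4e11 / 3e9)
  c3 <- preset_condition("COND3", 10)
  expect_equal(c3$initial_state[["n_P"]], 1e7)
  expect_equal(total_cells(c3$initial_state), 1e6)
  # presets are pure functions
  expect_identical(preset_condition("COND2B", 0.01),
                   preset_condition("COND2B", 0.01))
  expect_error(preset_condition("COND1", 7), "unknown variant")
  expect_error(preset_condition("CONDX", 1))
})

test_that("batch growth saturates at the resource budget", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND1", 0), p,
                             "conjugation_only")
  final <- total_cells_rows(traj$states)[length(traj$times)]
  budget <- min(3e9, 100 / 3.5e-8 + 1e6)
  expect_lt(abs(final - budget) / budget, 0.05)
  # resource is non-increasing while below carrying capacity
  expect_true(all(diff(traj$states[, "r"]) <= 1e-9))
  expect_true(all(traj$states >= 0))
})

test_that("empty cultures stay empty and the resource is untouched", {
  p <- tbl_params()
  cond <- experiment_condition(population_state(r = 100), duration = 200)
  for (sys in c("full", "conjugation_only", "infection_only")) {
    traj <- integrate_kinetics(cond, p, sys)
    expect_true(all(traj$states[, setdiff(colnames(traj$states), "r")] == 0))
    expect_equal(max(abs(traj$states[, "r"] - 100)), 0)
  }
  eo <- euler_oracle(cond, p, "full", dt = 0.5)
  expect_equal(eo$states, integrate_kinetics(cond, p, "full")$states)
})

test_that("high-phage infection wipes out susceptible donors", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND2B", 1), p,
                             "infection_only")
  i300 <- which(traj$times == 300)
  s <- traj$states[i300, ]
  expect_lt(s[["n_D"]], 1)               # donors effectively gone
  expect_gt(s[["n_I"]] / total_cells(s), 0.99)  # producers dominate
})

test_that("solution is independent of the reporting grid", {
  p <- tbl_params()
  c20 <- preset_condition("COND1", 1)
  c40 <- preset_condition("COND1", 1)
  c40$sampling_interval <- 40
  t20 <- integrate_kinetics(c20, p, "conjugation_only")
  t40 <- integrate_kinetics(c40, p, "conjugation_only")
  shared <- match(t40$times, t20$times)
  dev <- abs(t40$states - t20$states[shared, ]) /
    pmax(abs(t20$states[shared, ]), 1)
  expect_lt(max(dev), 1e-5)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  p <- tbl_params()
  cond <- preset_condition("COND3", 10)
  a <- integrate_kinetics(cond, p, "full", compiled = TRUE)
  b <- integrate_kinetics(cond, p, "full", compiled = FALSE)
  expect_lt(range_rel_dev(a, b), 1e-7)
})

test_that("the forward-Euler oracle converges at first order to lsoda", {
  p <- tbl_params()
  cond <- preset_condition("COND1", 1)
  cond$duration <- 300
  ref <- integrate_kinetics(cond, p, "conjugation_only")
  d1 <- norm_rel_dev(euler_oracle(cond, p, "conjugation_only", dt = 0.04),
                     ref)
  d2 <- norm_rel_dev(euler_oracle(cond, p, "conjugation_only", dt = 0.02),
                     ref)
  expect_lt(d2, d1)
  expect_gt(d1 / d2, 1.7)  # O(dt): halving the step about halves the error
  expect_lt(d1 / d2, 2.3)
})

test_that("Euler conserves the growth-free linear invariants", {
  p <- kinetic_params(psi_max = 0, lambda_T = 0, lambda_X = 0)
  cond <- experiment_condition(population_state(r = 100, n_D = 5e5,
                                                n_R = 5e5),
                               duration = 100, sampling_interval = 20)
  eo <- euler_oracle(cond, p, "conjugation_only", dt = 0.1)
  expect_equal(max(abs(eo$states[, "n_D"] + eo$states[, "n_X"] - 5e5)) / 5e5,
               0, tolerance = 1e-12)
  expect_equal(max(abs(eo$states[, "n_R"] + eo$states[, "n_T"] - 5e5)) / 5e5,
               0, tolerance = 1e-12)
})

test_that("trajectories round-trip through the TSV writer", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND2C", 0.1), p,
                             "infection_only")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_trajectory(traj, path)
  df <- read_trajectory(path)
  expect_equal(df$time_min, traj$times)
  expect_equal(as.matrix(df[, -1]), traj$states, ignore_attr = TRUE,
               tolerance = 1e-12)
})
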