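test_that("growth stage recovers psi_max and e from a pure-donor curve", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND1", 0), p, "full")
  data <- synthesize_dataset(traj, "tolC", noise_sd = 0, seed = 1)
  fit <- fit_growth(data)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["psi_max"]] - 0.035) / 0.035, 0.01)
  expect_lt(abs(coef(fit)[["e"]] - 3.5e-8) / 3.5e-8, 0.02)
  expect_equal(fit$n_observations, 36)
  expect_identical(sort(names(fit$fixed)),
                   sort(setdiff(names(kinetic_params()), c("psi_max", "e"))))
  # accepted objective values never increase
  expect_true(all(diff(fit$diagnostics$objective_trace) <= 0))
  r <- residuals(fit)
  expect_lt(max(abs(r)), 1e-4)
})

test_that("a flat growth curve drives psi_max to the boundary and is flagged", {
  times <- seq(0, 700, 20)
  flat <- marker_series("tolC", times, abundance = rep(1e6, length(times)),
                        condition = preset_condition("COND1", 0))
  fit <- fit_growth(flat)
  expect_lt(coef(fit)[["psi_max"]], 2e-4)
  expect_true(any(grepl("bound", fit$diagnostics$notes)))
})

test_that("conjugation stage recovers gamma_max jointly across ratios", {
  p <- tbl_params()
  b <- synthesize_bundle(p, noise_sd = 0, seed = 5)
  fit <- fit_conjugation(b$conjugation, params0 = p)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["gamma_max"]] - 3e-10) / 3e-10, 0.05)
  expect_length(fit$groups, 4L)
})

test_that("donor-only data leave the transfer rate unidentifiable, flagged", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND1", 0), p, "full")
  data <- synthesize_dataset(traj, c("tolC", "traI"), noise_sd = 0, seed = 1)
  fit <- fit_conjugation(data, params0 = p)
  expect_true(any(grepl("no recipients", fit$diagnostics$notes)))
  expect_true(any(grepl("fewer than 2 ratio datasets",
                        fit$diagnostics$notes)))
})

test_that("transfer-free data pin gamma_max to the lower bound", {
  p0 <- kinetic_params(gamma_max = 0)
  conds <- lapply(c(1, 10), function(v) preset_condition("COND1", v))
  data <- unlist(lapply(conds, function(cn) {
    synthesize_dataset(integrate_kinetics(cn, p0, "full"),
                       c("tolC", "traI"), noise_sd = 0, seed = 2)
  }), recursive = FALSE)
  fit <- fit_conjugation(data, params0 = tbl_params())
  expect_lt(coef(fit)[["gamma_max"]], 1e-12)
  expect_lt(fit$residual_norm, 1e-4)
  expect_true(any(grepl("bound", fit$diagnostics$notes)))
})

test_that("competition stage recovers the conjugation penalty", {
  p <- tbl_params()
  b <- synthesize_bundle(p, noise_sd = 0, seed = 5)
  fit <- fit_competition(b$competition, params0 = p)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["P_gamma"]] - 0.1) / 0.1, 0.10)
  # a penalty-free generator is recovered at the boundary value 1
  p1 <- kinetic_params(P_gamma = 1)
  b1 <- synthesize_bundle(p1, noise_sd = 0, seed = 6)
  fit1 <- fit_competition(b1$competition, params0 = p)
  expect_gt(coef(fit1)[["P_gamma"]], 0.9)
})

test_that("refits track perturbed generating values, not the defaults", {
  # growth: both parameters doubled / halved
  p_g <- kinetic_params(psi_max = 0.07, e = 1.75e-8)
  d <- synthesize_dataset(integrate_kinetics(preset_condition("COND1", 0),
                                             p_g, "full"),
                          "tolC", noise_sd = 0, seed = 1)
  f <- fit_growth(d)
  expect_lt(abs(coef(f)[["psi_max"]] - 0.07) / 0.07, 0.01)
  expect_lt(abs(coef(f)[["e"]] - 1.75e-8) / 1.75e-8, 0.02)
  # conjugation: transfer rate doubled
  p_c <- kinetic_params(gamma_max = 6e-10)
  b <- synthesize_bundle(p_c, noise_sd = 0, seed = 2)
  f2 <- fit_conjugation(b$conjugation, params0 = tbl_params())
  expect_lt(abs(coef(f2)[["gamma_max"]] - 6e-10) / 6e-10, 0.05)
  # competition: penalty doubled
  p_m <- kinetic_params(P_gamma = 0.2)
  b3 <- synthesize_bundle(p_m, noise_sd = 0, seed = 3)
  f3 <- fit_competition(b3$competition, params0 = tbl_params())
  expect_lt(abs(coef(f3)[["P_gamma"]] - 0.2) / 0.2, 0.10)
  # infection: infection rate doubled, production halved, penalty halved
  p_i <- kinetic_params(beta_max = 6e-11, psiP_max = 3, P_psi = 0.3)
  b4 <- synthesize_bundle(p_i, noise_sd = 0, seed = 4)
  f4 <- fit_infection(b4$infection, params0 = tbl_params())
  expect_lt(abs(coef(f4)[["beta_max"]] - 6e-11) / 6e-11, 0.10)
  expect_lt(abs(coef(f4)[["psiP_max"]] - 3) / 3, 0.10)
  expect_lt(abs(coef(f4)[["P_psi"]] - 0.3) / 0.3, 0.10)
})

test_that("phage-free data are flagged for the infection stage", {
  p <- tbl_params()
  d <- synthesize_dataset(integrate_kinetics(preset_condition("COND1", 0),
                                             p, "full"),
                          "tolC", noise_sd = 0, seed = 9)
  fit <- fit_infection(d, params0 = p, n_starts = 2L, maxit = 20L)
  expect_true(any(grepl("phage-free", fit$diagnostics$notes)))
})

test_that("calibration threads estimates and reports missing stages", {
  p <- tbl_params()
  b <- synthesize_bundle(p, noise_sd = 0, seed = 5)
  b$competition <- NULL
  cal <- run_full_calibration(b)
  expect_identical(unname(cal$status),
                   c("completed", "completed", "completed", "absent"))
  expect_lt(abs(cal$params[["beta_max"]] - 3e-11) / 3e-11, 0.10)
  expect_identical(
    cal$table$source[match("gamma_max", cal$table$parameter)],
    "fitted (conjugation)")
  expect_identical(cal$table$source[match("K", cal$table$parameter)],
                   "fixed")
  expect_named(coef(cal), c("psi_max", "e", "gamma_max", "beta_max",
                            "psiP_max", "P_psi"))
})

test_that("fit predictions line up with observations for noiseless data", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND1", 0), p, "full")
  data <- synthesize_dataset(traj, "tolC", noise_sd = 0, seed = 1)
  fit <- fit_growth(data)
  pr <- predict(fit, type = "log10")
  expect_equal(pr$fitted, pr$observed, tolerance = 1e-4)
  prc <- predict(fit, type = "ct")
  expect_equal(prc$observed, abundance_to_ct(data[[1]]$abundance),
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_identical(sims[[1]][[1]]$locus, "tolC")
  expect_false(identical(sims[[1]][[1]]$ct, sims[[2]][[1]]$ct))
})
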