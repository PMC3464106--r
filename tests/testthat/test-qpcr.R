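test_that("marker mapping reflects which compartments carry each locus", {
  p <- tbl_params()
  # recipients carry the chromosome but no F plasmid
  condR <- experiment_condition(population_state(r = 100, n_R = 1e6), 200)
  trajR <- integrate_kinetics(condR, p, "conjugation_only")
  expect_true(all(marker_abundance(trajR, "traI")$abundance == 0))
  expect_equal(marker_abundance(trajR, "tolC")$abundance,
               trajR$states[, "n_R"], ignore_attr = TRUE)
  # a pure donor culture has tolC = traI everywhere
  trajD <- integrate_kinetics(donor_only_condition(), p, "conjugation_only")
  expect_equal(marker_abundance(trajD, "tolC")$abundance,
               marker_abundance(trajD, "traI")$abundance)
  # counts are conserved: tolC = traI + recipients
  trajM <- integrate_kinetics(preset_condition("COND3", 10), p, "full")
  expect_equal(marker_abundance(trajM, "tolC")$abundance,
               marker_abundance(trajM, "traI")$abundance +
                 trajM$states[, "n_R"], ignore_attr = TRUE)
  expect_equal(marker_abundance(trajM, "M13")$abundance,
               trajM$states[, "n_P"], ignore_attr = TRUE)
})

test_that("saturated pre-infected cultures carry ~140 phage genomes per cell", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND2C", 1), p,
                             "infection_only")
  n <- length(traj$times)
  ratio <- marker_abundance(traj, "M13")$abundance[n] /
    marker_abundance(traj, "tolC")$abundance[n]
  expect_lt(abs(ratio - 4e11 / (100 / 3.5e-8)) / (4e11 / (100 / 3.5e-8)),
            0.10)
})

test_that("ideal Ct conversion is exact, invertible and censors zeros", {
  calib <- qpcr_calibration(ct_ref = 35, N_ref = 1e3)
  expect_equal(abundance_to_ct(1e3, calib), 35)
  expect_equal(abundance_to_ct(2e3, calib), 34)  # one doubling = one cycle
  # a 2^7 abundance ratio is a 7-cycle difference
  expect_equal(abundance_to_ct(1e5, calib) - abundance_to_ct(1e5 * 128, calib),
               7)
  # 10-fold abundance change is log2(10) cycles
  expect_equal(abundance_to_ct(1e4, calib) - abundance_to_ct(1e5, calib),
               log2(10))
  expect_true(is.na(abundance_to_ct(0, calib)))
  expect_true(is.na(abundance_to_ct(-3, calib)))
  N <- 10^runif(50, 0, 12)
  expect_equal(ct_to_abundance(abundance_to_ct(N, calib), calib), N)
  expect_equal(ct_to_abundance(35, calib), 1e3)
})

test_that("synthetic datasets are deterministic and noiseless-exact", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND2C", 0.1), p,
                             "infection_only")
  d1 <- synthesize_dataset(traj, c("tolC", "M13"), noise_sd = 0.5,
                           n_replicates = 2, seed = 7)
  d2 <- synthesize_dataset(traj, c("tolC", "M13"), noise_sd = 0.5,
                           n_replicates = 2, seed = 7)
  expect_identical(d1, d2)
  d3 <- synthesize_dataset(traj, c("tolC", "M13"), noise_sd = 0.5,
                           n_replicates = 2, seed = 8)
  expect_false(identical(d1[[1]]$ct, d3[[1]]$ct))
  # zero noise reproduces the ideal mapping exactly
  d0 <- synthesize_dataset(traj, "M13", noise_sd = 0, seed = 1)
  expect_equal(d0[[1]]$abundance, marker_abundance(traj, "M13")$abundance)
  expect_equal(ct_to_abundance(d0[[1]]$ct, qpcr_calibration()),
               marker_abundance(traj, "M13")$abundance)
  expect_error(synthesize_dataset(traj, character(0), seed = 1), "non-empty")
  expect_error(synthesize_dataset(traj, "tolC"), "seed")
})

test_that("cycle noise has the requested spread and never goes negative", {
  p <- tbl_params()
  cond <- experiment_condition(population_state(r = 100, n_D = 1e6), 20)
  traj <- integrate_kinetics(cond, p, "conjugation_only")
  ds <- synthesize_dataset(traj, "tolC", noise_sd = 0.5,
                           n_replicates = 1000, seed = 11)
  cts <- vapply(ds, function(s) s$ct[1], 0)
  expect_lt(abs(stats::sd(cts) - 0.5) / 0.5, 0.10)
  expect_true(all(vapply(ds, function(s) all(s$abundance >= 0), TRUE)))
})

test_that("datasets round-trip through delimited text with conditions", {
  p <- tbl_params()
  traj <- integrate_kinetics(preset_condition("COND1", 10), p,
                             "conjugation_only")
  ds <- synthesize_dataset(traj, c("tolC", "traI"), noise_sd = 0.3,
                           n_replicates = 2, seed = 3)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(length(back), length(ds))
  key <- function(x) paste(x$locus, x$replicate_id)
  back <- back[match(vapply(ds, key, ""), vapply(back, key, ""))]
  for (i in seq_along(ds)) {
    expect_equal(back[[i]]$times, ds[[i]]$times)
    expect_equal(back[[i]]$ct, ds[[i]]$ct, tolerance = 1e-6)
    expect_equal(unclass(back[[i]]$condition$initial_state),
                 unclass(ds[[i]]$condition$initial_state))
  }
})
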