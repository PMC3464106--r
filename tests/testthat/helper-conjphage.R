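# Shared fixtures: everything is generated in code at test time.

tbl_params <- function(...) kinetic_params(...)

# Max deviation between two trajectories, per compartment, scaled by that
# compartment's dynamic range (floor 1 unit): compartments that have decayed
# to sub-resolution values do not inflate the comparison.
range_rel_dev <- function(a, b) {
  stopifnot(identical(a$times, b$times))
  sc <- pmax(apply(b$states, 2, max), 1)
  max(sweep(abs(a$states - b$states), 2, sc, "/"))
}

# Max deviation scaled by the instantaneous culture magnitude (cells for the
# cell compartments, max(phage, cells) for phage, r0 for resource).
norm_rel_dev <- function(a, b, r0 = 100) {
  cells <- c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I", "n_XI")
  scale_cell <- pmax(rowSums(b$states[, cells, drop = FALSE]), 1)
  dev <- abs(a$states - b$states)
  rel <- dev
  rel[, cells] <- dev[, cells] / scale_cell
  rel[, "n_P"] <- dev[, "n_P"] / pmax(b$states[, "n_P"], scale_cell)
  rel[, "r"] <- dev[, "r"] / r0
  max(rel)
}

donor_only_condition <- function(n0 = 1e6, r0 = 100, duration = 700,
                                 interval = 20) {
  experiment_condition(population_state(r = r0, n_D = n0),
                       duration = duration, sampling_interval = interval)
}

total_cells_rows <- function(states) {
  rowSums(states[, c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I", "n_XI"),
                 drop = FALSE])
}
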