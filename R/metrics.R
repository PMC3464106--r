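#' Conjugation-to-infection encounter-rate ratio
#'
#' At the moment of mixing, donors conjugate at `gamma(r) n_D n_R` and are
#' infected at `beta(r) n_D n_P`; the donor density cancels, so the ratio of
#' the two encounter rates is `(gamma_max / beta_max) * (n_R / n_P)` (the
#' shared Monod factor cancels as well). A ratio above 1 means a donor is
#' more likely to meet a recipient and conjugate than to be hit by a phage.
#'
#' @param gamma_max Maximum conjugation rate, mL/cell/min (> 0).
#' @param beta_max Maximum phage infection rate, mL/phage/min (> 0).
#' @param n_R Recipient density, cells/mL (> 0).
#' @param n_P Free phage density, phages/mL (> 0).
#' @return List of class `ratio_report`: `gamma_over_beta`, `nR_over_nP`,
#'   `rate_ratio` (their product) and the echoed inputs.
#' @examples
#' conjugation_infection_ratio(3e-10, 3e-11, n_R = 1, n_P = 2)$rate_ratio
#' @export
conjugation_infection_ratio <- function(gamma_max, beta_max, n_R, n_P) {
  if (!is.finite(beta_max) || beta_max <= 0) stop("beta_max must be > 0")
  if (!is.finite(gamma_max) || gamma_max <= 0) stop("gamma_max must be > 0")
  if (!is.finite(n_P) || n_P <= 0) stop("n_P must be > 0")
  if (!is.finite(n_R) || n_R < 0) stop("n_R must be >= 0")
  gb <- gamma_max / beta_max
  rp <- n_R / n_P
  structure(list(gamma_over_beta = gb, nR_over_nP = rp,
                 rate_ratio = gb * rp,
                 inputs = list(gamma_max = gamma_max, beta_max = beta_max,
                               n_R = n_R, n_P = n_P)),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf(
    "Encounter-rate ratio: gamma/beta = %.4g x (n_R/n_P = %.4g) = %.4g\n",
    x$gamma_over_beta, x$nR_over_nP, x$rate_ratio))
  invisible(x)
}

#' Free phages per cell along a trajectory
#'
#' `n_P(t) / total cells(t)` at a requested time (nearest sampled point). In
#' a saturated pre-infected culture this is the per-cell phage burden the
#' two carrying capacities imply.
#'
#' @param traj A `kinetic_trajectory`.
#' @param t Time, min (defaults to the final sampling time).
#' @return Phages per cell (dimensionless); `NA` if no cells are present.
#' @export
phages_per_cell <- function(traj, t = max(traj$times)) {
  if (t < min(traj$times) || t > max(traj$times))
    stop("t outside the trajectory time range")
  i <- which.min(abs(traj$times - t))
  cells <- total_cells(traj$states[i, ])
  if (cells <= 0) return(NA_real_)
  unname(traj$states[i, "n_P"] / cells)
}

#' Ct-difference series between two marker loci
#'
#' Ideal `Ct(locus_a) - Ct(locus_b)` per time point, which equals
#' `log2(N_b / N_a)`; when both loci share the calibration anchor, the
#' anchor cancels and the series depends only on the abundance ratio. Times
#' where either locus is censored (zero abundance) are omitted.
#'
#' @param traj A `kinetic_trajectory`.
#' @param locus_a,locus_b Marker loci (see [marker_abundance()]).
#' @param calib [qpcr_calibration()] (cancels out; kept for interface
#'   symmetry).
#' @return List: `times`, `dct` (cycles) at the retained times, and
#'   `n_censored`.
#' @examples
#' traj <- integrate_kinetics(preset_condition("COND2C", 1),
#'                            kinetic_params(), "infection_only")
#' dct <- ct_difference_series(traj, "tolC", "M13")
#' tail(dct$dct, 1)  # ~log2(phages per cell)
#' @export
ct_difference_series <- function(traj, locus_a, locus_b,
                                 calib = qpcr_calibration()) {
  a <- marker_abundance(traj, locus_a)$abundance
  b <- marker_abundance(traj, locus_b)$abundance
  ct_a <- abundance_to_ct(a, calib)
  ct_b <- abundance_to_ct(b, calib)
  keep <- !is.na(ct_a) & !is.na(ct_b)
  list(times = traj$times[keep], dct = ct_a[keep] - ct_b[keep],
       n_censored = sum(!keep))
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Rescales one kinetic parameter by a set of multipliers, re-simulates the
#' condition, and summarises the marker curve by its initial log-slope and
#' its time to half-saturation. The initial slope is the least-squares slope
#' of log10 abundance over the first `slope_window` minutes (positive
#' abundances only); half-saturation is the first sampled time at which the
#' marker reaches half of its own final value.
#'
#' @param param_name One of the [kinetic_params()] names.
#' @param multipliers Positive multipliers applied to the baseline value.
#' @param condition An [experiment_condition()].
#' @param params Baseline [kinetic_params()].
#' @param locus Marker locus to summarise (default `"M13"`).
#' @param system ODE system to integrate (default `"full"`).
#' @param slope_window Initial window for the log-slope, min (default 100).
#' @return List with `summary` (data frame: multiplier, value, initial
#'   log-slope per min, time to half-saturation, final abundance) and
#'   `trajectories` (one `kinetic_trajectory` per multiplier).
#' @export
sensitivity_sweep <- function(param_name, multipliers, condition, params,
                              locus = "M13", system = "full",
                              slope_window = 100) {
  params <- as_kinetic_params(params)
  if (!param_name %in% param_names()) stop("unknown parameter: ", param_name)
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  trajs <- list()
  rows <- lapply(seq_along(multipliers), function(i) {
    m <- multipliers[i]
    value <- params[[param_name]] * m
    p <- as_kinetic_params(set_params(params, stats::setNames(value,
                                                              param_name)))
    traj <- integrate_kinetics(condition, p, system = system)
    trajs[[i]] <<- traj
    ab <- marker_abundance(traj, locus)$abundance
    w <- traj$times <= slope_window & ab > 0
    slope <- if (sum(w) >= 2L)
      stats::coef(stats::lm(log10(ab[w]) ~ traj$times[w]))[[2L]]
    else NA_real_
    final <- ab[length(ab)]
    t_half <- if (final > 0) traj$times[which(ab >= final / 2)[1L]]
              else NA_real_
    data.frame(multiplier = m, value = value, initial_log_slope = slope,
               t_half_saturation = t_half, final_abundance = final)
  })
  list(summary = do.call(rbind, rows), trajectories = trajs,
       param_name = param_name, locus = locus)
}

#' Time at which culture growth effectively saturates
#'
#' First sampled time at which the total-cell growth rate falls below
#' `1e-3 * psi_max * K` per minute (reported alongside "saturation" taken
#' operationally as the final sampling time).
#'
#' @param traj A `kinetic_trajectory`.
#' @param params [kinetic_params()] (for the threshold).
#' @return Time in min, or `NA` if growth never slows below the threshold.
#' @export
saturation_time <- function(traj, params = traj$params) {
  tot <- rowSums(traj$states[, c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I",
                                 "n_XI"), drop = FALSE])
  if (length(tot) < 2L) return(NA_real_)
  rate <- diff(tot) / diff(traj$times)
  thr <- 1e-3 * params[["psi_max"]] * params[["K"]]
  peak <- which.max(rate)
  if (rate[peak] < thr) return(NA_real_)  # growth never takes off
  i <- which(rate < thr & seq_along(rate) >= peak)[1L]
  if (is.na(i)) NA_real_ else traj$times[i + 1L]
}
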