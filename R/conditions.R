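#' Define a flask experiment
#'
#' An experiment condition bundles the inoculation state of one 50-mL flask,
#' the simulated duration and the aliquot sampling interval.
#'
#' @param initial_state A [population_state()] at t = 0. The default resource
#'   pool for fresh Luria broth is 100 a.u. (with `Q = 1` a.u.).
#' @param duration Total simulated time, min (> 0).
#' @param sampling_interval Aliquot interval, min; the bench protocol sampled
#'   every 15 or 20 min.
#' @param label Condition identifier; one of `"COND1"`, `"COND2A"`,
#'   `"COND2B"`, `"COND2C"`, `"COND3"` for the standard presets (see
#'   [preset_condition()]) or `"CUSTOM"`.
#' @param variant The preset variant (mixing ratio or dilution), if any.
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(initial_state, duration,
                                 sampling_interval = 20,
                                 label = "CUSTOM", variant = NA_real_) {
  validate_population_state(unclass(initial_state))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be > 0")
  structure(list(label = label, variant = variant,
                 initial_state = initial_state, duration = duration,
                 sampling_interval = sampling_interval),
            class = "experiment_condition")
}

#' @export
print.experiment_condition <- function(x, ...) {
  cat(sprintf("Experiment condition %s (variant %s): %g min, sampled every %g min\n",
              x$label, format(x$variant), x$duration, x$sampling_interval))
  nz <- unclass(x$initial_state)
  nz <- nz[nz > 0]
  cat("  inoculum:", paste(sprintf("%s = %.3g", names(nz), nz), collapse = ", "),
      "\n")
  invisible(x)
}

# Densities implied by the pipetting protocol, assuming an overnight
# saturated culture sits at the cell carrying capacity K = 3e9 cells/mL and a
# revived phage stock at its measured titer 1e11 phages/mL.
OVERNIGHT_CELLS <- 3e9
PHAGE_STOCK <- 1e11
R0_DEFAULT <- 100

#' Standard flask inoculation presets
#'
#' Reconstructs the five bench conditions as initial states:
#' \describe{
#'   \item{COND1}{Conjugation without phage: donor/recipient mixtures at a
#'     total of 1e6 cells/mL, split D:R = 1:`variant` for
#'     `variant` in 0 (pure donor), 1, 10, 100, 1000; 700 min.}
#'   \item{COND2A}{Fixed phage inoculum (1e7 phages/mL, i.e. 5 uL of a 1e11
#'     stock in 50 mL) against serially diluted donors:
#'     `n_D = 3e7 * variant` cells/mL for `variant` in 1, 0.1, 0.01; 500 min.}
#'   \item{COND2B}{Fixed donors (3e6 cells/mL, 50 uL of saturated culture in
#'     50 mL) against serially diluted phage: `n_P = 1e8 * variant` for
#'     `variant` in 1 .. 1e-4; 500 min.}
#'   \item{COND2C}{Pre-infected overnight culture diluted as a whole:
#'     `n_I = 1.2e7 * variant`, `n_P = 1.6e9 * variant` (saturated culture at
#'     K and K_P scaled by the 0.2/50 transfer) for `variant` in 1, 0.1,
#'     0.01; 500 min. The overnight pre-infection far exceeds the 30-min
#'     latency, so the inoculum is placed in the producing class `n_I`.}
#'   \item{COND3}{The COND1 mixtures plus phage at 1e7 phages/mL added at
#'     t = 0; 700 min.}
#' }
#' All presets start from a fresh resource pool of 100 a.u. and sample every
#' 20 min. Presets are pure functions of `(label, variant)`.
#'
#' @param label One of `"COND1"`, `"COND2A"`, `"COND2B"`, `"COND2C"`,
#'   `"COND3"`.
#' @param variant Mixing ratio (COND1/COND3: recipients per donor) or
#'   dilution factor (COND2A/2B/2C); must be one of the values listed above.
#' @return An [experiment_condition()].
#' @examples
#' preset_condition("COND1", 1)     # 1:1 donor:recipient mixture
#' preset_condition("COND2B", 0.1)  # donors vs 1e7 phages/mL
#' @export
preset_condition <- function(label, variant) {
  label <- match.arg(label, c("COND1", "COND2A", "COND2B", "COND2C", "COND3"))
  ok <- preset_variants(label)
  if (length(variant) != 1L || !any(abs(variant - ok) <= 1e-9 * pmax(ok, 1)))
    stop(sprintf("unknown variant %s for %s; choose one of: %s",
                 format(variant), label, paste(ok, collapse = ", ")))
  mix <- function(ratio) { # D:R = 1:ratio at 1e6 total cells/mL
    tot <- 1e6
    list(n_D = tot / (1 + ratio), n_R = tot * ratio / (1 + ratio))
  }
  s <- switch(label,
    COND1 = {
      m <- mix(variant)
      population_state(r = R0_DEFAULT, n_D = m$n_D, n_R = m$n_R)
    },
    COND2A = population_state(r = R0_DEFAULT,
                              n_D = OVERNIGHT_CELLS * (0.5 / 50) * variant,
                              n_P = PHAGE_STOCK * (5e-3 / 50)),
    COND2B = population_state(r = R0_DEFAULT,
                              n_D = OVERNIGHT_CELLS * (0.05 / 50),
                              n_P = PHAGE_STOCK * (0.05 / 50) * variant),
    COND2C = population_state(r = R0_DEFAULT,
                              n_I = OVERNIGHT_CELLS * (0.2 / 50) * variant,
                              n_P = 4e11 * (0.2 / 50) * variant),
    COND3 = {
      m <- mix(variant)
      population_state(r = R0_DEFAULT, n_D = m$n_D, n_R = m$n_R,
                       n_P = PHAGE_STOCK * (5e-3 / 50))
    })
  duration <- if (label %in% c("COND1", "COND3")) 700 else 500
  experiment_condition(s, duration = duration, sampling_interval = 20,
                       label = label, variant = variant)
}

#' Preset variants of a condition label
#'
#' @param label A preset label (see [preset_condition()]).
#' @return Numeric vector of the documented variants, in bench order.
#' @export
preset_variants <- function(label) {
  label <- match.arg(label, c("COND1", "COND2A", "COND2B", "COND2C", "COND3"))
  switch(label,
         COND1 = c(0, 1, 10, 100, 1000),
         COND2A = c(1, 0.1, 0.01),
         COND2B = c(1, 0.1, 0.01, 0.001, 1e-4),
         COND2C = c(1, 0.1, 0.01),
         COND3 = c(0, 1, 10, 100, 1000))
}

# The natural reduced system for a preset family (used by staged fitting).
preset_system <- function(label) {
  switch(label,
         COND1 = "conjugation_only",
         COND2A = , COND2B = , COND2C = "infection_only",
         COND3 = , CUSTOM = "full")
}
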