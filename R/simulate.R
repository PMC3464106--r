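#' Integrate the kinetic model over a sampling grid
#'
#' Solves the chosen ODE system with deSolve's stiff-capable `lsoda` from the
#' condition's inoculation state, reporting the state at every aliquot time.
#' Integration runs in the raw coordinates exactly as the equations are
#' written; small negative overshoot (within `1e6 * atol` below zero) is
#' clamped to zero on output, anything worse aborts with the first offending
#' time.
#'
#' @param condition An [experiment_condition()] or preset label understood by
#'   [preset_condition()] together with `variant`.
#' @param params A [kinetic_params()].
#' @param system `"full"` (9 variables), `"conjugation_only"` (r, n_D, n_R,
#'   n_T, n_X) or `"infection_only"` (r, n_D, n_N, n_I, n_P). The reductions
#'   require the excluded compartments to be empty at t = 0.
#' @param times Optional explicit output times (min, starting at 0);
#'   overrides the condition's sampling grid.
#' @param rtol,atol Relative / absolute integration tolerances (defaults
#'   1e-8 and 1e-2 cells/mL).
#' @param compiled Use the compiled right-hand sides (default); set `FALSE`
#'   to integrate the pure-R equations instead.
#' @return A `kinetic_trajectory`: list with `times`, a `states` matrix (one
#'   row per time, all nine variables; excluded compartments identically
#'   zero), `params`, `condition` and `system`.
#' @examples
#' traj <- integrate_kinetics(preset_condition("COND1", 0), kinetic_params())
#' head(as.data.frame(traj))
#' @export
integrate_kinetics <- function(condition, params, system = c("full",
                               "conjugation_only", "infection_only"),
                               times = NULL, rtol = 1e-8, atol = 1e-2,
                               compiled = TRUE) {
  system <- match.arg(system)
  params <- as_kinetic_params(params)
  y_full <- as_full_state_vector(condition$initial_state)
  vars <- switch(system, full = state_names(),
                 conjugation_only = conj_vars(), infection_only = inf_vars())
  off <- setdiff(state_names(), vars)
  if (any(y_full[off] != 0))
    stop(sprintf("system '%s' requires zero initial %s", system,
                 paste(off[y_full[off] != 0], collapse = ", ")))
  if (is.null(times)) {
    times <- seq(0, condition$duration, by = condition$sampling_interval)
    if (times[length(times)] < condition$duration)
      times <- c(times, condition$duration)
  } else {
    if (is.unsorted(times, strictly = TRUE) || times[1L] < 0)
      stop("times must be strictly increasing and start at >= 0")
    if (times[1L] > 0) times <- c(0, times)
  }
  y0 <- y_full[vars]
  p <- unclass(params)
  if (compiled) {
    func <- switch(system, full = "conjphage_derivs_full",
                   conjugation_only = "conjphage_derivs_conj",
                   infection_only = "conjphage_derivs_inf")
    sol <- deSolve::lsoda(y = y0, times = times, func = func, parms = p,
                          dllname = "conjphage",
                          initfunc = "conjphage_initmod",
                          rtol = rtol, atol = atol)
  } else {
    idx <- match(vars, state_names())
    rfun <- function(t, y, parms) {
      yy <- numeric(9L); yy[idx] <- y
      list(rhs_full(yy, parms)[idx])
    }
    sol <- deSolve::lsoda(y = y0, times = times, func = rfun, parms = p,
                          rtol = rtol, atol = atol)
  }
  istate <- attr(sol, "istate")[1L]
  if (!is.null(istate) && istate < 0 || nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) >= 1L) times[min(nrow(sol) + 1L, length(times))]
              else times[1L]
    stop(sprintf("integration failed near t = %g min (istate %s)",
                 t_fail, format(istate)))
  }
  y <- sol[, vars, drop = FALSE]
  if (min(y) < -1e6 * atol)
    stop(sprintf(
      "integration produced a coordinate below -1e6*atol (min %.4g) near t = %g min",
      min(y), times[which(apply(y, 1L, min) == min(y))[1L]]))
  y[y < 0] <- 0
  states <- matrix(0, nrow = length(times), ncol = 9L,
                   dimnames = list(NULL, state_names()))
  states[, vars] <- y
  structure(list(times = times, states = states, params = params,
                 condition = condition, system = system),
            class = "kinetic_trajectory")
}

#' Fixed-step forward-Euler oracle
#'
#' Integrates the same equations with plain forward Euler at a fixed step,
#' through the pure-R right-hand side. Deliberately naive: it exists to
#' cross-validate [integrate_kinetics()] (which uses adaptive `lsoda` on
#' compiled code) by an independent numerical route.
#'
#' @inheritParams integrate_kinetics
#' @param dt Euler step, min (> 0); sampling times are snapped onto the step
#'   grid.
#' @return A `kinetic_trajectory` (states clamped at zero like the main
#'   integrator).
#' @export
euler_oracle <- function(condition, params, system = c("full",
                         "conjugation_only", "infection_only"), dt = 0.01) {
  system <- match.arg(system)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  params <- as_kinetic_params(params)
  p <- unclass(params)
  y <- as_full_state_vector(condition$initial_state)
  vars <- switch(system, full = state_names(),
                 conjugation_only = conj_vars(), infection_only = inf_vars())
  off_idx <- which(!(state_names() %in% vars))
  if (any(y[off_idx] != 0))
    stop(sprintf("system '%s' requires zero initial compartments", system))
  times <- seq(0, condition$duration, by = condition$sampling_interval)
  if (times[length(times)] < condition$duration)
    times <- c(times, condition$duration)
  nsteps <- round(times / dt)
  states <- matrix(0, nrow = length(times), ncol = 9L,
                   dimnames = list(NULL, state_names()))
  states[1L, ] <- y
  step <- nsteps[1L]
  keep <- if (length(off_idx)) {
    function(v) { v[off_idx] <- 0; v } # freeze excluded compartments
  } else identity
  for (k in 2L:length(times)) {
    target <- nsteps[k]
    while (step < target) {
      y <- y + dt * rhs_full(y, p)
      y <- keep(y)
      step <- step + 1L
    }
    states[k, ] <- y
  }
  states[states < 0] <- 0
  structure(list(times = nsteps * dt, states = states, params = params,
                 condition = condition, system = system),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  final <- x$states[nrow(x$states), ]
  cat(sprintf("Kinetic trajectory: %s system, condition %s (variant %s)\n",
              x$system, x$condition$label, format(x$condition$variant)))
  cat(sprintf("  %d time points over %g min\n", length(x$times),
              x$times[length(x$times)]))
  cat(sprintf("  final: r = %.3g a.u., total cells = %.3g /mL, phage = %.3g /mL\n",
              final["r"], total_cells(final), final["n_P"]))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$states, check.names = FALSE)
}

#' @export
plot.kinetic_trajectory <- function(x, vars = c("n_D", "n_R", "n_T", "n_P"),
                                    log = "y", ...) {
  df <- as.data.frame(x)
  vars <- intersect(vars, colnames(x$states))
  y <- df[, vars, drop = FALSE]
  y[y <= 0] <- NA
  graphics::matplot(df$time_min, y, type = "l", lty = 1, log = log,
                    xlab = "time (min)", ylab = "density (per mL)", ...)
  graphics::legend("bottomright", legend = vars, lty = 1,
                   col = seq_along(vars), bty = "n")
  invisible(x)
}

#' Write / read a trajectory as tab-separated text
#'
#' Columns `time_min` then the nine state variables, one row per sampling
#' time, header mandatory.
#'
#' @param traj A `kinetic_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame with the same columns.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("time_min", state_names())
  if (!all(need %in% colnames(df)))
    stop("trajectory file must have columns: ", paste(need, collapse = ", "))
  df[, need]
}
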