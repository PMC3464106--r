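#' @importFrom stats optim coef residuals simulate
NULL

# Stage definitions: which parameters are freed, which reduced system is
# integrated, and which marker loci inform the residuals.
stage_spec <- function(stage) {
  switch(stage,
    growth = list(free = c("psi_max", "e"), system = "conjugation_only",
                  loci = "tolC"),
    conjugation = list(free = "gamma_max", system = "conjugation_only",
                       loci = c("tolC", "traI")),
    infection = list(free = c("beta_max", "psiP_max", "P_psi"),
                     system = "infection_only", loci = c("tolC", "M13")),
    competition = list(free = "P_gamma", system = "full",
                       loci = c("tolC", "traI", "M13")),
    stop("unknown stage: ", stage))
}

# Search bounds (log-uniform) for every parameter that is ever fitted.
fit_bounds <- function() {
  list(psi_max = c(1e-4, 1), e = c(1e-10, 1e-6),
       gamma_max = c(1e-14, 1e-7), beta_max = c(1e-15, 1e-8),
       psiP_max = c(1e-2, 1e2), P_psi = c(1e-3, 1), P_gamma = c(1e-3, 1))
}

# Model abundance floor (copies/mL) used only inside the objective so that a
# candidate driving a marker to zero is penalised smoothly instead of
# producing -Inf residuals.
MODEL_FLOOR <- 1e-3

# Organise marker series into condition groups sharing one forward solve.
build_fit_groups <- function(data, spec, calib) {
  if (inherits(data, "marker_series")) data <- list(data)
  data <- Filter(function(s) s$locus %in% spec$loci, data)
  if (!length(data))
    stop("no series with loci ", paste(spec$loci, collapse = "/"),
         " in the data")
  keys <- vapply(data, function(s) {
    if (is.null(s$condition))
      stop("every fitted marker_series needs its experiment condition attached")
    paste(c(s$condition$label, format(s$condition$variant, digits = 15),
            format(unclass(s$condition$initial_state), digits = 15),
            s$condition$duration), collapse = "|")
  }, "")
  groups <- lapply(split(seq_along(data), keys), function(idx) {
    times <- sort(unique(unlist(lapply(data[idx], function(s) s$times))))
    series <- lapply(data[idx], function(s) {
      obs <- if (!is.null(s$abundance)) s$abundance
             else ct_to_abundance(s$ct, calib)
      keep <- is.finite(obs) & obs > 0
      list(locus = s$locus, idx = match(s$times[keep], times),
           log_obs = log10(obs[keep]))
    })
    list(condition = data[[idx[1L]]]$condition, times = times,
         series = series)
  })
  list(groups = unname(groups), data = data,
       n_obs = sum(vapply(groups, function(g)
       sum(vapply(g$series, function(s) length(s$log_obs), 0L)), 0)))
}

marker_from_states <- function(states, locus) {
  switch(locus,
    tolC = rowSums(states[, c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I",
                              "n_XI"), drop = FALSE]),
    traI = rowSums(states[, c("n_D", "n_T", "n_X", "n_N", "n_I", "n_XI"),
                   drop = FALSE]),
    M13 = states[, "n_P"])
}

# Pooled sum of squared log10-abundance residuals at a candidate parameter
# vector (plain numeric, canonical order).
stage_ssr <- function(pvec, groups, system, rtol, atol) {
  total <- 0
  for (g in groups) {
    traj <- tryCatch(
      integrate_kinetics(g$condition, as_kinetic_params(pvec),
                         system = system, times = g$times,
                         rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(traj)) return(1e12)
    tidx <- match(g$times, traj$times)
    for (s in g$series) {
      model <- marker_from_states(traj$states, s$locus)[tidx][s$idx]
      total <- total + sum((log10(pmax(model, MODEL_FLOOR)) - s$log_obs)^2)
    }
  }
  total
}

#' Fit one calibration stage of the kinetic model
#'
#' The central estimator. Each stage frees a small, experimentally
#' identifiable subset of the kinetic parameters and fits it by ordinary
#' least squares on log10 marker abundance (equivalently, linearly in ideal
#' Ct), pooling the residuals of every series handed in. Forward model
#' evaluations integrate the stage's natural reduced system under each
#' series' experiment condition. Optimisation is bounded quasi-Newton
#' (`optim` L-BFGS-B) on log10-transformed parameters with five log-spaced
#' starts; the best converged start wins.
#'
#' Stages and their free parameters:
#' \describe{
#'   \item{growth}{`psi_max`, `e` from a pure-donor tolC curve.}
#'   \item{conjugation}{`gamma_max` from donor:recipient ratio mixtures
#'     (tolC + traI), jointly.}
#'   \item{infection}{`beta_max`, `psiP_max`, `P_psi` from the two phage
#'     infection families (tolC + M13), jointly.}
#'   \item{competition}{`P_gamma` from the mixed conjugation + phage
#'     flasks (all three loci).}
#' }
#' Everything not freed is held at its value in `params0`. Censored or zero
#' observations are excluded from the residuals, never log-transformed.
#'
#' @param data A [marker_series()] or list of them, each carrying its
#'   [experiment_condition()]. Loci not used by the stage are ignored.
#' @param stage One of `"growth"`, `"conjugation"`, `"infection"`,
#'   `"competition"`.
#' @param params0 [kinetic_params()] supplying the fixed parameters (and
#'   nothing else: free parameters start from the log-spaced grid, not from
#'   `params0`).
#' @param calib [qpcr_calibration()] used when a series carries only Ct.
#' @param n_starts Number of log-spaced multi-starts (default 5).
#' @param maxit Iteration cap per start (default 500).
#' @param rtol,atol Integration tolerances for the forward solves.
#' @return An object of class `kinetic_fit` with the estimates, the fixed
#'   parameters, the pooled residual norm, convergence diagnostics
#'   (iterations, termination message, best-so-far objective trace, boundary
#'   and identifiability notes) and the updated full parameter set. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' \donttest{
#' traj <- integrate_kinetics(preset_condition("COND1", 0), kinetic_params())
#' data <- synthesize_dataset(traj, "tolC", noise_sd = 0, seed = 1)
#' fit <- fit_kinetics(data, "growth")
#' coef(fit)
#' }
#' @export
fit_kinetics <- function(data, stage = c("growth", "conjugation", "infection",
                                         "competition"),
                         params0 = kinetic_params(),
                         calib = qpcr_calibration(), n_starts = 5L,
                         maxit = 500L, rtol = 1e-8, atol = 1e-2) {
  stage <- match.arg(stage)
  spec <- stage_spec(stage)
  params0 <- as_kinetic_params(params0)
  fd <- build_fit_groups(data, spec, calib)
  notes <- identifiability_notes(stage, fd$groups)

  bounds <- fit_bounds()[spec$free]
  lo <- log10(vapply(bounds, `[`, 0, 1L))
  hi <- log10(vapply(bounds, `[`, 0, 2L))
  p0 <- unclass(params0)

  env <- new.env()
  env$n_eval <- 0L
  env$best <- Inf
  env$trace <- numeric()
  obj <- function(theta) {
    pvec <- p0
    pvec[spec$free] <- 10^theta
    val <- stage_ssr(pvec, fd$groups, spec$system, rtol, atol)
    env$n_eval <- env$n_eval + 1L
    if (val < env$best) {
      env$best <- val
      env$trace <- c(env$trace, val)
    }
    val
  }

  runs <- lapply(seq_len(n_starts), function(k) {
    start <- lo + k / (n_starts + 1) * (hi - lo)
    tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = maxit, factr = 1e5)),
      error = function(e) list(par = start, value = Inf, convergence = 99L,
                               message = conditionMessage(e),
                               counts = c(0L, 0L)))
  })
  values <- vapply(runs, function(r) r$value, 0)
  best <- runs[[which.min(values)]]
  converged <- identical(best$convergence, 0L)
  termination <- if (converged) "converged"
                 else paste0("code ", best$convergence, ": ",
                             if (is.null(best$message)) "" else best$message)
  # L-BFGS-B can stall in its line search at the optimum when the numerical
  # gradient is dominated by adaptive-integrator noise; a restart that finds
  # no further improvement confirms convergence.
  if (!converged && is.finite(best$value)) {
    retry <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lo,
                   upper = hi, control = list(maxit = maxit, factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(retry) && retry$value <= best$value) {
      no_gain <- (best$value - retry$value) <= 1e-8 * (1 + abs(best$value))
      if (retry$value < best$value) best <- retry
      if (identical(retry$convergence, 0L) || no_gain) {
        converged <- TRUE
        termination <- "converged (line-search stall at optimum, restart confirmed)"
      }
    }
  }

  estimates <- stats::setNames(10^best$par, spec$free)
  at_bound <- spec$free[best$par <= lo + 1e-8 | best$par >= hi - 1e-8]
  if (length(at_bound))
    notes <- c(notes, paste0("estimate at search bound: ",
                             paste(at_bound, collapse = ", ")))
  fitted_params <- as_kinetic_params(set_params(params0, estimates))

  structure(list(
    stage = stage,
    estimates = estimates,
    fixed = p0[setdiff(param_names(), spec$free)],
    residual_norm = best$value,
    n_observations = fd$n_obs,
    converged = converged,
    diagnostics = list(
      iterations = best$counts[1L],
      n_evaluations = env$n_eval,
      termination = termination,
      start_values = values,
      objective_trace = env$trace,
      notes = notes),
    params = fitted_params,
    system = spec$system,
    calib = calib,
    data = fd$data,
    groups = fd$groups), class = "kinetic_fit")
}

identifiability_notes <- function(stage, groups) {
  notes <- character()
  inits <- lapply(groups, function(g) unclass(g$condition$initial_state))
  if (stage == "conjugation") {
    if (length(groups) < 2L)
      notes <- c(notes,
                 "fewer than 2 ratio datasets: gamma_max weakly identifiable")
    if (all(vapply(inits, function(s) s[["n_R"]] == 0, TRUE)))
      notes <- c(notes, "no recipients in any condition: no transfer signal,
 gamma_max unidentifiable")
  }
  if (stage == "infection" &&
      all(vapply(inits, function(s)
        s[["n_P"]] == 0 && s[["n_I"]] == 0 && s[["n_N"]] == 0, TRUE)))
    notes <- c(notes,
               "phage-free data: beta_max/psiP_max/P_psi unidentifiable")
  if (stage == "competition" &&
      all(vapply(inits, function(s)
        s[["n_R"]] == 0 || (s[["n_P"]] == 0 && s[["n_I"]] == 0), TRUE)))
    notes <- c(notes, "no condition mixes recipients with phage: P_gamma
 weakly identifiable")
  gsub("\n", "", notes)
}

#' Stage-specific fitting wrappers
#'
#' Convenience wrappers around [fit_kinetics()] for the four calibration
#' stages: `fit_growth` frees `psi_max` and `e`, `fit_conjugation` frees
#' `gamma_max`, `fit_infection` frees `beta_max`, `psiP_max` and `P_psi`,
#' and `fit_competition` frees `P_gamma`.
#'
#' @inheritParams fit_kinetics
#' @param ... Passed on to [fit_kinetics()].
#' @return A `kinetic_fit` (see [fit_kinetics()]).
#' @export
fit_growth <- function(data, params0 = kinetic_params(), ...) {
  fit_kinetics(data, "growth", params0 = params0, ...)
}

#' @rdname fit_growth
#' @export
fit_conjugation <- function(data, params0 = kinetic_params(), ...) {
  fit_kinetics(data, "conjugation", params0 = params0, ...)
}

#' @rdname fit_growth
#' @export
fit_infection <- function(data, params0 = kinetic_params(), ...) {
  fit_kinetics(data, "infection", params0 = params0, ...)
}

#' @rdname fit_growth
#' @export
fit_competition <- function(data, params0 = kinetic_params(), ...) {
  fit_kinetics(data, "competition", params0 = params0, ...)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit, stage '%s' (%s system)\n", x$stage, x$system))
  cat("  estimates:\n")
  for (nm in names(x$estimates))
    cat(sprintf("    %-10s %.6g %s\n", nm, x$estimates[[nm]],
                param_units()[[nm]]))
  cat(sprintf("  residual norm (log10 space): %.6g over %d observations\n",
              x$residual_norm, x$n_observations))
  cat(sprintf("  converged: %s (%s)\n", x$converged,
              x$diagnostics$termination))
  if (length(x$diagnostics$notes))
    cat("  notes:", paste(x$diagnostics$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d condition group(s); %d optimiser starts (objective %s)\n",
              length(object$groups), length(object$diagnostics$start_values),
              paste(signif(object$diagnostics$start_values, 4),
                    collapse = ", ")))
  r <- residuals(object)
  cat(sprintf("  residuals (log10): min %.3g, median %.3g, max %.3g\n",
              min(r), stats::median(r), max(r)))
  invisible(object)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$estimates

#' Model predictions for a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param newdata Optional list of [marker_series()] (with conditions) to
#'   predict for; defaults to the fitted data.
#' @param type `"abundance"` (copies/mL), `"log10"` or `"ct"`.
#' @param ... Unused.
#' @return A data frame with columns `condition`, `variant`, `locus`,
#'   `replicate_id`, `time_min`, `observed`, `fitted` (on the requested
#'   scale; censored observations are `NA`).
#' @export
predict.kinetic_fit <- function(object, newdata = NULL,
                                type = c("abundance", "log10", "ct"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  spec <- stage_spec(object$stage)
  out <- lapply(data, function(s) {
    traj <- integrate_kinetics(s$condition, object$params,
                               system = spec$system, times = s$times)
    model <- marker_from_states(traj$states, s$locus)[match(s$times,
                                                            traj$times)]
    obs <- if (!is.null(s$abundance)) s$abundance
           else ct_to_abundance(s$ct, object$calib)
    conv <- switch(type,
                   abundance = identity,
                   log10 = function(v) ifelse(v > 0, log10(v), NA_real_),
                   ct = function(v) abundance_to_ct(v, object$calib))
    data.frame(condition = s$condition$label, variant = s$condition$variant,
               locus = s$locus, replicate_id = s$replicate_id,
               time_min = s$times, observed = conv(obs),
               fitted = conv(model))
  })
  do.call(rbind, out)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  pr <- predict(object, type = "log10")
  keep <- is.finite(pr$observed) & is.finite(pr$fitted)
  pr$observed[keep] - pr$fitted[keep]
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  pr <- predict(x, type = "log10")
  loci <- unique(pr$locus)
  op <- graphics::par(mfrow = c(1, length(loci)))
  on.exit(graphics::par(op))
  for (lc in loci) {
    sub <- pr[pr$locus == lc, ]
    grp <- interaction(sub$condition, sub$variant, sub$replicate_id)
    graphics::plot(sub$time_min, sub$observed, col = as.integer(grp),
                   pch = 1, xlab = "time (min)",
                   ylab = "log10 copies/mL", main = lc, ...)
    for (g in levels(grp)) {
      gs <- sub[grp == g, ]
      graphics::lines(gs$time_min, gs$fitted, col = which(levels(grp) == g))
    }
  }
  invisible(x)
}

#' Simulate synthetic replicate datasets from a fitted stage
#'
#' Draws new noisy qPCR datasets from the fitted parameters under the same
#' experiment conditions as the fitted data.
#'
#' @param object A `kinetic_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param noise_sd Ct noise sd, cycles (default 0.5).
#' @param ... Unused.
#' @return A list of `nsim` datasets (each a list of [marker_series()]).
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = 1, noise_sd = 0.5,
                                 ...) {
  spec <- stage_spec(object$stage)
  lapply(seq_len(nsim), function(i) {
    out <- list()
    for (g in object$groups) {
      traj <- integrate_kinetics(g$condition, object$params,
                                 system = spec$system)
      loci <- unique(vapply(g$series, function(s) s$locus, ""))
      out <- c(out, synthesize_dataset(traj, loci, noise_sd = noise_sd,
                                       n_replicates = 1L,
                                       seed = seed + 131L * i,
                                       calib = object$calib))
    }
    out
  })
}

#' Run the full four-stage calibration
#'
#' Executes growth, conjugation, infection and competition fits in order,
#' threading each stage's estimates into the fixed parameters of the next,
#' exactly as the staged experimental design intends. A non-convergent stage
#' aborts the downstream stages; a stage with no data is reported absent and
#' skipped (downstream stages still run, using `params0` values for its
#' parameters).
#'
#' @param bundle Named list with any of the elements `growth`,
#'   `conjugation`, `infection`, `competition`, each a list of
#'   [marker_series()] with conditions attached (see
#'   [synthesize_bundle()]).
#' @param params0 [kinetic_params()] holding the never-fitted constants
#'   (`lambda_T`, `lambda_X`, `lambda_N`, `K`, `K_P`, `Q`).
#' @param ... Passed to [fit_kinetics()].
#' @return An object of class `kinetic_calibration`: list of `kinetic_fit`s,
#'   per-stage `status` (`completed` / `absent` / `failed` / `aborted`), the
#'   final threaded [kinetic_params()], and a consolidated parameter table.
#' @export
run_full_calibration <- function(bundle, params0 = kinetic_params(), ...) {
  stages <- c("growth", "conjugation", "infection", "competition")
  fits <- list()
  status <- stats::setNames(rep("pending", 4L), stages)
  params <- as_kinetic_params(params0)
  aborted <- FALSE
  for (st in stages) {
    if (aborted) { status[[st]] <- "aborted"; next }
    if (is.null(bundle[[st]])) { status[[st]] <- "absent"; next }
    fit <- fit_kinetics(bundle[[st]], st, params0 = params, ...)
    fits[[st]] <- fit
    if (!fit$converged) {
      status[[st]] <- "failed"
      aborted <- TRUE
    } else {
      status[[st]] <- "completed"
      params <- fit$params
    }
  }
  fitted_by <- stats::setNames(rep(NA_character_, 13L), param_names())
  for (st in names(fits))
    if (status[[st]] == "completed")
      fitted_by[names(fits[[st]]$estimates)] <- st
  tab <- data.frame(parameter = param_names(),
                    value = unname(unclass(params)),
                    unit = unname(param_units()),
                    source = ifelse(is.na(fitted_by), "fixed",
                                    paste0("fitted (", fitted_by, ")")))
  structure(list(fits = fits, status = status, params = params, table = tab),
            class = "kinetic_calibration")
}

#' @export
print.kinetic_calibration <- function(x, ...) {
  cat("Staged kinetic calibration\n")
  for (st in names(x$status))
    cat(sprintf("  %-12s %s\n", st, x$status[[st]]))
  tab <- x$table
  tab$value <- signif(tab$value, 6)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.kinetic_calibration <- function(object, ...) {
  do.call(c, unname(lapply(object$fits, function(f) f$estimates)))
}

#' @export
summary.kinetic_calibration <- function(object, ...) {
  print(object)
  for (f in object$fits) {
    cat("\n")
    print(f)
  }
  invisible(object)
}
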