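#' Kinetic parameters of the conjugation/infection model
#'
#' Container for every rate constant, capacity, lag rate and penalty factor of
#' the resource-limited conjugation + M13 infection model. Defaults are the
#' calibrated values for the W6 (F+)/W6 (F-) system in Luria broth at 37 C.
#'
#' @param psi_max Maximum cell growth rate, 1/min.
#' @param gamma_max Maximum conjugation rate, mL/cell/min.
#' @param beta_max Maximum phage infection rate, mL/phage/min. Folds together
#'   surface binding, genome entry and establishment; the qPCR assay this
#'   model was built for cannot distinguish them.
#' @param psiP_max Maximum phage production (secretion) rate, phages/cell/min.
#' @param Q Resource concentration at half-maximal rate, arbitrary units
#'   (a.u.); all four rate laws share it.
#' @param e Resource consumed per cell division, a.u. mL/cell.
#' @param K Cell carrying capacity, cells/mL.
#' @param K_P Phage carrying capacity, phages/mL.
#' @param lambda_T Rate at which a transconjugant matures into an active
#'   donor, 1/min (mean delay 90 min).
#' @param lambda_X Rate at which an exhausted donor (infected or not)
#'   recovers the ability to donate, 1/min (mean delay 30 min).
#' @param lambda_N Rate at which a newly infected cell becomes an active
#'   phage producer, 1/min (latent period 30 min).
#' @param P_psi Growth-rate penalty factor on infected cells, in (0, 1].
#' @param P_gamma Conjugation-rate penalty factor on infected donors, in
#'   (0, 1]. The alias `P_lambda` is accepted (same quantity under another
#'   name in some configurations).
#' @param ... Only the alias `P_lambda` is accepted here; anything else is an
#'   error.
#'
#' @return An object of class `kinetic_params`: a named numeric vector of the
#'   13 constants in a fixed order.
#' @examples
#' kinetic_params()
#' kinetic_params(gamma_max = 6e-10, P_lambda = 0.2)
#' @export
kinetic_params <- function(psi_max = 0.035,
                           gamma_max = 3e-10,
                           beta_max = 3e-11,
                           psiP_max = 6,
                           Q = 1,
                           e = 3.5e-8,
                           K = 3e9,
                           K_P = 4e11,
                           lambda_T = 1 / 90,
                           lambda_X = 1 / 30,
                           lambda_N = 1 / 30,
                           P_psi = 0.6,
                           P_gamma = 0.1,
                           ...) {
  dots <- list(...)
  if (length(dots)) {
    if (!all(names(dots) %in% "P_lambda")) {
      stop("unknown kinetic parameter(s): ",
           paste(setdiff(names(dots), "P_lambda"), collapse = ", "))
    }
    if (!missing(P_gamma) && !is.null(dots$P_lambda)) {
      stop("supply either 'P_gamma' or its alias 'P_lambda', not both")
    }
    P_gamma <- dots$P_lambda
  }
  p <- c(psi_max = psi_max, gamma_max = gamma_max, beta_max = beta_max,
         psiP_max = psiP_max, Q = Q, e = e, K = K, K_P = K_P,
         lambda_T = lambda_T, lambda_X = lambda_X, lambda_N = lambda_N,
         P_psi = P_psi, P_gamma = P_gamma)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

param_names <- function() {
  c("psi_max", "gamma_max", "beta_max", "psiP_max", "Q", "e", "K", "K_P",
    "lambda_T", "lambda_X", "lambda_N", "P_psi", "P_gamma")
}

validate_kinetic_params <- function(p) {
  if (!is.numeric(p) || length(p) != 13L || !identical(names(p), param_names()))
    stop("kinetic_params must hold the 13 named constants in canonical order")
  if (any(!is.finite(p))) stop("kinetic parameters must be finite")
  if (any(p[c("Q", "e", "K", "K_P")] <= 0))
    stop("Q, e and the carrying capacities must be > 0")
  if (any(p < 0)) stop("rate constants must be >= 0")
  if (p[["P_psi"]] <= 0 || p[["P_psi"]] > 1 ||
      p[["P_gamma"]] <= 0 || p[["P_gamma"]] > 1)
    stop("penalty factors P_psi and P_gamma must lie in (0, 1]")
  invisible(p)
}

#' Coerce to kinetic parameters
#'
#' @param x A `kinetic_params` object, or a named numeric vector / list whose
#'   names are a subset of the parameter names (unnamed entries are an error);
#'   missing parameters take their defaults. `P_lambda` is accepted as an
#'   alias for `P_gamma`.
#' @return A `kinetic_params` object.
#' @export
as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) {
    validate_kinetic_params(unclass(x))
    return(x)
  }
  x <- as.list(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("parameters must be named")
  do.call(kinetic_params, x)
}

param_units <- function() {
  c(psi_max = "1/min", gamma_max = "mL/cell/min", beta_max = "mL/phage/min",
    psiP_max = "phages/cell/min", Q = "a.u.", e = "a.u. mL/cell",
    K = "cells/mL", K_P = "phages/mL", lambda_T = "1/min",
    lambda_X = "1/min", lambda_N = "1/min", P_psi = "", P_gamma = "")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (conjugation + M13 infection model)\n")
  df <- data.frame(value = signif(unclass(x), 6),
                   unit = param_units()[names(x)])
  print(df)
  invisible(x)
}

# Update a parameter set, returning a plain numeric vector in canonical order
# (used in optimisation inner loops where re-validation would cost time).
set_params <- function(params, values) {
  p <- unclass(params)
  p[names(values)] <- values
  p
}
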