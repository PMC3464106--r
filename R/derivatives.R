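#' Hyperbolic (Monod) rate law
#'
#' All four kinetic rates of the model -- cell growth, conjugation, phage
#' infection and phage production -- depend on the remaining resource through
#' the same saturating form `rate_max * r / (Q + r)`, the Monod analogue of
#' Michaelis-Menten kinetics. The rate is half-maximal at r = Q and
#' approaches rate_max as r grows.
#'
#' @param r Resource concentration, a.u. (vectorised; must be >= 0).
#' @param rate_max Maximum rate (any unit; must be >= 0).
#' @param Q Resource concentration at half-maximum, a.u. (must be > 0).
#' @return The resource-limited rate, same unit as `rate_max`.
#' @examples
#' hyperbolic_rate(1, 0.035, 1)    # half-maximal growth
#' hyperbolic_rate(100, 0.035, 1)  # near-maximal
#' @export
hyperbolic_rate <- function(r, rate_max, Q) {
  if (any(!is.finite(r)) || any(r < 0)) stop("resource r must be finite and >= 0")
  if (!is.finite(Q) || Q <= 0) stop("half-saturation Q must be > 0")
  if (any(!is.finite(rate_max)) || any(rate_max < 0)) stop("rate_max must be >= 0")
  rate_max * r / (Q + r)
}

# Internal unchecked RHS of the full 9-variable system, shared by the exported
# derivative operations and the forward-Euler oracle. `y` and the return value
# are plain numeric vectors in canonical state order; `p` a plain numeric
# vector in canonical parameter order. Kept independent of the compiled C
# right-hand sides so the two implementations can cross-check each other.
rhs_full <- function(y, p) {
  r <- y[1L]; nD <- y[2L]; nR <- y[3L]; nT <- y[4L]; nX <- y[5L]
  nN <- y[6L]; nI <- y[7L]; nXI <- y[8L]; nP <- y[9L]

  s <- r / (p[5L] + r)
  psi <- p[1L] * s
  gam <- p[2L] * s
  bet <- p[3L] * s
  psiP <- p[4L] * s
  sumn <- nD + nR + nT + nX + nN + nI + nXI
  L <- 1 - sumn / p[7L]
  conj <- gam * nD * nR
  conjI <- p[13L] * gam * nI * nR
  inf <- bet * nD * nP

  c(-p[6L] * psi * (nD + nR + nT + nX) * L -
      p[6L] * p[12L] * psi * (nN + nI + nXI) * L,
    psi * nD * L - conj + p[10L] * nX + p[9L] * nT - inf,
    psi * nR * L - conj - conjI,
    psi * nT * L + conj - p[9L] * nT + conjI,
    psi * nX * L + conj - p[10L] * nX,
    p[12L] * psi * nN * L + inf - p[11L] * nN,
    p[12L] * psi * nI * L + p[11L] * nN - conjI + p[10L] * nXI,
    p[12L] * psi * nXI * L + conjI - p[10L] * nXI,
    psiP * (nI + nXI) * (1 - nP / p[8L]))
}

conj_vars <- function() c("r", "n_D", "n_R", "n_T", "n_X")
inf_vars <- function() c("r", "n_D", "n_N", "n_I", "n_P")

# Accept a full population_state or a named sub-vector; return the full
# 9-vector with unnamed compartments at zero.
as_full_state_vector <- function(state) {
  y <- stats::setNames(numeric(9L), state_names())
  state <- unclass(state)
  if (is.null(names(state))) {
    if (length(state) != 9L) stop("unnamed state must have all 9 variables")
    names(state) <- state_names()
  }
  unknown <- setdiff(names(state), state_names())
  if (length(unknown)) stop("unknown state variable(s): ",
                            paste(unknown, collapse = ", "))
  y[names(state)] <- state
  if (any(!is.finite(y))) stop("state variables must be finite")
  y
}

#' Time derivatives of the full conjugation + infection system
#'
#' Evaluates the right-hand side of the nine-variable model: resource
#' depletion by dividing cells (infected classes consume at the growth
#' penalty `P_psi`), logistic crowding through `(1 - total cells / K)`,
#' mass-action conjugation `gamma(r) n_D n_R` (penalised to
#' `P_gamma gamma(r) n_I n_R` for infected donors), mass-action infection
#' `beta(r) n_D n_P`, first-order maturation/recovery lags, and phage
#' production by producing classes saturating at `K_P`.
#'
#' @param state A [population_state()] (named vectors with a subset of the
#'   state variables are accepted; omitted compartments are zero).
#' @param params A [kinetic_params()].
#' @return Named numeric vector of the nine time derivatives (per minute).
#' @seealso [derivatives_conjugation_only()], [derivatives_infection_only()]
#' @export
derivatives_full <- function(state, params) {
  y <- as_full_state_vector(state)
  p <- unclass(as_kinetic_params(params))
  stats::setNames(rhs_full(y, p), state_names())
}

#' Time derivatives of the conjugation-only reduction
#'
#' The five-variable system (`r`, `n_D`, `n_R`, `n_T`, `n_X`) that governs a
#' phage-free culture. Computed by evaluating the full system with all
#' phage-side compartments at zero, so the reduction is consistent with
#' [derivatives_full()] by construction.
#'
#' @inheritParams derivatives_full
#' @return Named numeric vector of the five derivatives.
#' @export
derivatives_conjugation_only <- function(state, params) {
  y <- as_full_state_vector(state)
  if (any(y[c("n_N", "n_I", "n_XI", "n_P")] != 0))
    stop("conjugation-only reduction requires zero phage-side compartments")
  derivatives_full(y, params)[conj_vars()]
}

#' Time derivatives of the infection-only reduction
#'
#' The five-variable system (`r`, `n_D`, `n_N`, `n_I`, `n_P`) that governs a
#' donor-only infected culture with no recipients. Evaluated through the full
#' system at `n_R = n_T = n_X = n_XI = 0` (with no recipients, the exhausted
#' infected compartment never populates, so phage production from `n_I`
#' alone is exact).
#'
#' @inheritParams derivatives_full
#' @return Named numeric vector of the five derivatives.
#' @export
derivatives_infection_only <- function(state, params) {
  y <- as_full_state_vector(state)
  if (any(y[c("n_R", "n_T", "n_X", "n_XI")] != 0))
    stop("infection-only reduction requires zero conjugation-side compartments")
  derivatives_full(y, params)[inf_vars()]
}
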