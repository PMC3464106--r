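#' Population state of the batch culture
#'
#' One instant of the culture: the resource pool plus the seven cell
#' compartments and free phage. All densities are per mL of culture.
#'
#' @param r Resource concentration, arbitrary units (a.u.).
#' @param n_D Active (uninfected) donor cells, cells/mL.
#' @param n_R Recipient (plasmid-free) cells, cells/mL.
#' @param n_T Transconjugants (recipients that just received the plasmid),
#'   cells/mL.
#' @param n_X Temporarily exhausted donors (just donated), cells/mL.
#' @param n_N Newly infected cells (not yet producing phage), cells/mL.
#' @param n_I Actively phage-producing infected cells, cells/mL.
#' @param n_XI Exhausted infected donors, cells/mL.
#' @param n_P Free M13 phage, phages/mL.
#' @return An object of class `population_state`: a named numeric vector of
#'   the nine variables.
#' @examples
#' population_state(r = 100, n_D = 1e6)
#' @export
population_state <- function(r = 0, n_D = 0, n_R = 0, n_T = 0, n_X = 0,
                             n_N = 0, n_I = 0, n_XI = 0, n_P = 0) {
  s <- c(r = r, n_D = n_D, n_R = n_R, n_T = n_T, n_X = n_X,
         n_N = n_N, n_I = n_I, n_XI = n_XI, n_P = n_P)
  validate_population_state(s)
  structure(s, class = "population_state")
}

state_names <- function() {
  c("r", "n_D", "n_R", "n_T", "n_X", "n_N", "n_I", "n_XI", "n_P")
}

validate_population_state <- function(s) {
  if (!is.numeric(s) || length(s) != 9L || !identical(names(s), state_names()))
    stop("population_state must hold the 9 named variables in canonical order")
  if (any(!is.finite(s))) stop("state variables must be finite")
  if (any(s < 0)) stop("state variables must be non-negative")
  invisible(s)
}

#' Total cell density of a state
#'
#' Sum of the seven cell compartments (donors, recipients, transconjugants,
#' exhausted donors, and the three infected classes); excludes free phage.
#'
#' @param state A [population_state()] (or named vector with the cell fields).
#' @return Total cells/mL.
#' @export
total_cells <- function(state) {
  sum(state[c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I", "n_XI")])
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state (resource a.u.; cells and phage per mL)\n")
  print(signif(unclass(x), 6))
  invisible(x)
}
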