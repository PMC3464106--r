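#' Load and validate a run configuration
#'
#' Configurations are YAML or JSON with the blocks `parameters` (any
#' [kinetic_params()] field, `P_lambda` accepted as alias for `P_gamma`),
#' `condition` (either `preset:`/`variant:` or an explicit `initial_state`,
#' `duration`, `sampling_interval`), `integration` (`system`, `rtol`,
#' `atol`), `synthesis` (`loci`, `noise_sd`, `n_replicates`, `seed`,
#' `ct_ref`, `N_ref`) and `output` (paths). Unknown keys anywhere are
#' rejected; a seed is mandatory whenever `noise_sd > 0`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or a list with the
#'   same structure.
#' @return A validated list of class `run_config` with all defaults filled
#'   in.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")
  known_blocks <- c("parameters", "condition", "integration", "synthesis",
                    "output")
  reject_unknown(cfg, known_blocks, "top level")

  pars <- cfg$parameters
  if (!is.null(pars)) {
    reject_unknown(pars, c(param_names(), "P_lambda"), "parameters")
    params <- as_kinetic_params(lapply(pars, as.numeric))
  } else params <- kinetic_params()

  cnd <- cfg$condition
  if (is.null(cnd)) stop("config needs a 'condition' block")
  reject_unknown(cnd, c("preset", "variant", "initial_state", "duration",
                        "sampling_interval"), "condition")
  condition <- if (!is.null(cnd$preset)) {
    cond <- preset_condition(cnd$preset, as.numeric(cnd$variant))
    if (!is.null(cnd$duration)) cond$duration <- as.numeric(cnd$duration)
    if (!is.null(cnd$sampling_interval))
      cond$sampling_interval <- as.numeric(cnd$sampling_interval)
    cond
  } else {
    if (is.null(cnd$initial_state) || is.null(cnd$duration))
      stop("custom condition needs 'initial_state' and 'duration'")
    reject_unknown(cnd$initial_state, state_names(),
                   "condition$initial_state")
    experiment_condition(
      do.call(population_state, lapply(cnd$initial_state, as.numeric)),
      duration = as.numeric(cnd$duration),
      sampling_interval = if (is.null(cnd$sampling_interval)) 20
                          else as.numeric(cnd$sampling_interval))
  }

  intg <- if (is.null(cfg$integration)) list() else cfg$integration
  reject_unknown(intg, c("system", "rtol", "atol"), "integration")
  integration <- list(
    system = if (is.null(intg$system)) "full" else
      match.arg(intg$system, c("full", "conjugation_only",
                               "infection_only")),
    rtol = if (is.null(intg$rtol)) 1e-8 else as.numeric(intg$rtol),
    atol = if (is.null(intg$atol)) 1e-2 else as.numeric(intg$atol))

  syn <- if (is.null(cfg$synthesis)) list() else cfg$synthesis
  reject_unknown(syn, c("loci", "noise_sd", "n_replicates", "seed",
                        "ct_ref", "N_ref"), "synthesis")
  synthesis <- list(
    loci = if (is.null(syn$loci)) MARKER_LOCI else unlist(syn$loci),
    noise_sd = if (is.null(syn$noise_sd)) 0.5 else as.numeric(syn$noise_sd),
    n_replicates = if (is.null(syn$n_replicates)) 1L
                   else as.integer(syn$n_replicates),
    seed = if (is.null(syn$seed)) NULL else as.integer(syn$seed),
    calib = qpcr_calibration(
      ct_ref = if (is.null(syn$ct_ref)) 35 else as.numeric(syn$ct_ref),
      N_ref = if (is.null(syn$N_ref)) 1e3 else as.numeric(syn$N_ref)))
  if (!is.null(cfg$synthesis) && synthesis$noise_sd > 0 &&
      is.null(synthesis$seed))
    stop("a seed is mandatory whenever noise_sd > 0")

  out <- if (is.null(cfg$output)) list() else cfg$output
  reject_unknown(out, c("trajectory", "dataset_dir"), "output")

  structure(list(parameters = params, condition = condition,
                 integration = integration, synthesis = synthesis,
                 output = out),
            class = "run_config")
}

reject_unknown <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
  invisible()
}

resolved_config_list <- function(config) {
  list(package_version = as.character(utils::packageVersion("conjphage")),
       parameters = as.list(unclass(config$parameters)),
       condition = condition_to_list(config$condition),
       integration = config$integration,
       synthesis = list(loci = config$synthesis$loci,
                        noise_sd = config$synthesis$noise_sd,
                        n_replicates = config$synthesis$n_replicates,
                        seed = config$synthesis$seed,
                        ct_ref = config$synthesis$calib$ct_ref,
                        N_ref = config$synthesis$calib$N_ref))
}

#' Config-driven simulation and synthesis runs
#'
#' `run_simulation` integrates the configured condition and writes the
#' trajectory as TSV plus a JSON sidecar echoing the fully resolved
#' configuration (including the package version), so a run is reproducible
#' from its outputs alone. `run_synthesis` additionally converts the
#' trajectory into a synthetic qPCR dataset directory. Reruns with the same
#' config are byte-identical.
#'
#' @param config A `run_config` (or a path / list accepted by
#'   [load_run_config()]).
#' @param out Output file (`run_simulation`) or directory (`run_synthesis`);
#'   falls back to the config's `output` block.
#' @return The trajectory (`run_simulation`) or dataset (`run_synthesis`),
#'   invisibly.
#' @export
run_simulation <- function(config, out = NULL) {
  config <- if (inherits(config, "run_config")) config
            else load_run_config(config)
  traj <- integrate_kinetics(config$condition, config$parameters,
                             system = config$integration$system,
                             rtol = config$integration$rtol,
                             atol = config$integration$atol)
  out <- out %||% config$output$trajectory
  if (!is.null(out)) {
    write_trajectory(traj, out)
    jsonlite::write_json(resolved_config_list(config),
                         paste0(out, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(traj)
}

#' @rdname run_simulation
#' @export
run_synthesis <- function(config, out = NULL) {
  config <- if (inherits(config, "run_config")) config
            else load_run_config(config)
  traj <- run_simulation(config, out = NULL)
  syn <- config$synthesis
  if (syn$noise_sd > 0 && is.null(syn$seed))
    stop("a seed is mandatory whenever noise_sd > 0")
  dataset <- synthesize_dataset(traj, syn$loci, noise_sd = syn$noise_sd,
                                n_replicates = syn$n_replicates,
                                seed = syn$seed %||% 1L, calib = syn$calib)
  out <- out %||% config$output$dataset_dir
  if (!is.null(out)) {
    write_dataset(dataset, out)
    jsonlite::write_json(resolved_config_list(config),
                         file.path(out, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
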