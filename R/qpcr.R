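#' qPCR calibration constants
#'
#' The idealised threshold-cycle model assumes perfect doubling efficiency:
#' `Ct = ct_ref - log2(N / N_ref)`. The anchor is arbitrary but fixed;
#' because every locus shares it, Ct differences between loci depend only on
#' abundance ratios.
#'
#' @param ct_ref Reference threshold cycle (default 35).
#' @param N_ref Abundance at the reference cycle, copies/mL (default 1e3).
#' @return A list of class `qpcr_calibration`.
#' @export
qpcr_calibration <- function(ct_ref = 35, N_ref = 1e3) {
  if (!is.finite(ct_ref)) stop("ct_ref must be finite")
  if (!is.finite(N_ref) || N_ref <= 0) stop("N_ref must be > 0")
  structure(list(ct_ref = ct_ref, N_ref = N_ref), class = "qpcr_calibration")
}

MARKER_LOCI <- c("tolC", "traI", "M13")

#' Marker time series
#'
#' One qPCR marker track: a locus, its sampling times, and abundance and/or
#' Ct values. `tolC` (chromosomal) counts every cell, `traI` (F-plasmid)
#' counts plasmid-bearing cells, `M13` counts free phage genomes.
#'
#' @param locus `"tolC"`, `"traI"` or `"M13"`.
#' @param times Strictly increasing sampling times, min.
#' @param abundance Copies/mL (optional if `ct` given); must be >= 0.
#' @param ct Threshold cycles (optional if `abundance` given); `NA` marks a
#'   censored (no-amplification) point.
#' @param replicate_id Integer replicate label (default 1).
#' @param condition Optional [experiment_condition()] the series was measured
#'   under (carried as metadata; required for model fitting).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(locus, times, abundance = NULL, ct = NULL,
                          replicate_id = 1L, condition = NULL) {
  locus <- match.arg(locus, MARKER_LOCI)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is.null(abundance) && is.null(ct))
    stop("at least one of abundance / ct must be present")
  if (!is.null(abundance)) {
    if (length(abundance) != length(times)) stop("abundance length mismatch")
    if (any(abundance < 0, na.rm = TRUE)) stop("abundance must be >= 0")
  }
  if (!is.null(ct) && length(ct) != length(times)) stop("ct length mismatch")
  structure(list(locus = locus, times = as.numeric(times),
                 abundance = abundance, ct = ct,
                 replicate_id = as.integer(replicate_id),
                 condition = condition),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("Marker series: %s, replicate %d, %d points (%g-%g min)%s\n",
              x$locus, x$replicate_id, length(x$times), min(x$times),
              max(x$times),
              if (!is.null(x$condition))
                sprintf(", condition %s/%s", x$condition$label,
                        format(x$condition$variant)) else ""))
  invisible(x)
}

#' Map a trajectory onto a qPCR marker locus
#'
#' `tolC` reports all seven cell compartments (one chromosomal copy per
#' cell), `traI` all plasmid-bearing compartments (donors, transconjugants,
#' exhausted and infected classes; one F copy per cell), `M13` the free
#' phage pool.
#'
#' @param traj A `kinetic_trajectory`.
#' @param locus `"tolC"`, `"traI"` or `"M13"`.
#' @return A [marker_series()] with abundances (copies/mL) on the
#'   trajectory's sampling grid.
#' @export
marker_abundance <- function(traj, locus) {
  locus <- match.arg(locus, MARKER_LOCI)
  s <- traj$states
  ab <- switch(locus,
    tolC = rowSums(s[, c("n_D", "n_R", "n_T", "n_X", "n_N", "n_I", "n_XI"),
                     drop = FALSE]),
    traI = rowSums(s[, c("n_D", "n_T", "n_X", "n_N", "n_I", "n_XI"),
                     drop = FALSE]),
    M13 = s[, "n_P"])
  marker_series(locus, traj$times, abundance = unname(ab),
                condition = traj$condition)
}

#' Convert abundance to ideal threshold cycle and back
#'
#' Perfect-efficiency conversion: one cycle per doubling. Non-positive
#' abundances have no finite Ct and return the censored sentinel `NA`.
#'
#' @param N Abundance, copies/mL (vectorised).
#' @param calib A [qpcr_calibration()].
#' @return Threshold cycles (`abundance_to_ct`) or copies/mL
#'   (`ct_to_abundance`).
#' @examples
#' calib <- qpcr_calibration()
#' abundance_to_ct(2e3, calib)            # one doubling above the anchor
#' ct_to_abundance(abundance_to_ct(5e6, calib), calib)
#' @export
abundance_to_ct <- function(N, calib = qpcr_calibration()) {
  ct <- rep(NA_real_, length(N))
  pos <- is.finite(N) & N > 0
  ct[pos] <- calib$ct_ref - log2(N[pos] / calib$N_ref)
  ct
}

#' @rdname abundance_to_ct
#' @param ct Threshold cycles (vectorised; `NA` stays `NA`).
#' @export
ct_to_abundance <- function(ct, calib = qpcr_calibration()) {
  calib$N_ref * 2^(calib$ct_ref - ct)
}

# Deterministic substream seed for (locus, replicate): keeps every draw
# reproducible from one user seed while decoupling loci and replicates.
substream_seed <- function(seed, locus_idx, replicate) {
  (as.integer(seed) %% 1000003L) * 1009L + locus_idx * 101L + replicate
}

#' Generate a synthetic qPCR dataset from a trajectory
#'
#' Converts the trajectory to ideal Ct per locus and adds i.i.d. Gaussian
#' cycle noise, the error structure of replicate flask qPCR series (replicate
#' ranges stay within about one cycle at the default sd of 0.5). Noise lives
#' in Ct (log2) space only, so back-converted abundances are multiplicative
#' log-normal and never negative. Censored points (zero abundance) stay
#' censored.
#'
#' @param traj A `kinetic_trajectory`.
#' @param loci Character vector of loci to synthesise (non-empty).
#' @param noise_sd Ct noise standard deviation, cycles (>= 0; default 0.5).
#' @param n_replicates Replicate series per locus (default 1).
#' @param seed Integer seed; mandatory, every (locus, replicate) substream is
#'   derived from it, so a fixed seed gives identical output.
#' @param calib A [qpcr_calibration()].
#' @return List of [marker_series()] (loci vary fastest over replicates),
#'   each with both `ct` and back-converted `abundance`, carrying the
#'   trajectory's condition.
#' @export
synthesize_dataset <- function(traj, loci = MARKER_LOCI, noise_sd = 0.5,
                               n_replicates = 1L, seed,
                               calib = qpcr_calibration()) {
  if (length(loci) == 0L) stop("loci must be non-empty")
  loci <- vapply(loci, match.arg, "", choices = MARKER_LOCI)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing(seed) || !is.finite(seed)) stop("an explicit seed is required")
  out <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (locus in loci) {
      ideal <- marker_abundance(traj, locus)
      ct0 <- abundance_to_ct(ideal$abundance, calib)
      locus_idx <- match(locus, MARKER_LOCI)
      if (noise_sd > 0) {
        set.seed(substream_seed(seed, locus_idx, rep_i))
        ct <- ct0 + stats::rnorm(length(ct0), 0, noise_sd)
      } else ct <- ct0
      ab <- ifelse(is.na(ct), 0, ct_to_abundance(ct, calib))
      out[[length(out) + 1L]] <-
        marker_series(locus, traj$times, abundance = ab, ct = ct,
                      replicate_id = rep_i, condition = traj$condition)
    }
  }
  out
}

#' Write / read marker-series datasets as delimited text
#'
#' One file per dataset, columns `locus, replicate_id, time_min, ct,
#' abundance` (tab-separated, empty field = missing). `write_dataset` also
#' writes a `conditions.json` sidecar so conditions survive the round trip;
#' `read_dataset` restores them when the sidecar is present.
#'
#' @param dataset A list of [marker_series()].
#' @param path Output file (for `write_marker_series`) or directory (for
#'   `write_dataset`).
#' @return The path, invisibly (writers); a list of [marker_series()]
#'   (readers).
#' @export
write_marker_series <- function(dataset, path) {
  if (inherits(dataset, "marker_series")) dataset <- list(dataset)
  rows <- lapply(dataset, function(s) {
    data.frame(locus = s$locus, replicate_id = s$replicate_id,
               time_min = s$times,
               ct = if (is.null(s$ct)) NA_real_ else s$ct,
               abundance = if (is.null(s$abundance)) NA_real_ else s$abundance)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_marker_series
#' @export
read_marker_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "",
                          check.names = FALSE)
  need <- c("locus", "replicate_id", "time_min")
  if (!all(need %in% colnames(df)))
    stop("marker file must have columns locus, replicate_id, time_min")
  groups <- split(df, list(df$locus, df$replicate_id), drop = TRUE)
  lapply(unname(groups), function(g) {
    g <- g[order(g$time_min), ]
    marker_series(g$locus[1L], g$time_min,
                  abundance = if ("abundance" %in% colnames(g)) g$abundance,
                  ct = if ("ct" %in% colnames(g)) g$ct,
                  replicate_id = g$replicate_id[1L])
  })
}

#' @rdname write_marker_series
#' @export
write_dataset <- function(dataset, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write_marker_series(dataset, file.path(path, "markers.tsv"))
  conds <- list()
  for (s in dataset) {
    if (!is.null(s$condition))
      conds[[paste(s$locus, s$replicate_id, sep = ":")]] <-
        condition_to_list(s$condition)
  }
  jsonlite::write_json(conds, file.path(path, "conditions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_marker_series
#' @export
read_dataset <- function(path) {
  dataset <- read_marker_series(file.path(path, "markers.tsv"))
  sidecar <- file.path(path, "conditions.json")
  if (file.exists(sidecar)) {
    conds <- jsonlite::read_json(sidecar)
    for (i in seq_along(dataset)) {
      key <- paste(dataset[[i]]$locus, dataset[[i]]$replicate_id, sep = ":")
      if (!is.null(conds[[key]]))
        dataset[[i]]$condition <- condition_from_list(conds[[key]])
    }
  }
  dataset
}

condition_to_list <- function(cond) {
  list(label = cond$label, variant = cond$variant,
       initial_state = as.list(unclass(cond$initial_state)),
       duration = cond$duration, sampling_interval = cond$sampling_interval)
}

condition_from_list <- function(x) {
  experiment_condition(
    do.call(population_state, lapply(x$initial_state, as.numeric)),
    duration = as.numeric(x$duration),
    sampling_interval = as.numeric(x$sampling_interval),
    label = x$label,
    variant = if (is.null(x$variant)) NA_real_ else as.numeric(x$variant))
}
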