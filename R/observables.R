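# Emission spectra, secondary electron yield (SEY) and backscattering
# coefficient (BC). SEY and BC are computed by direct counting with the
# 50 eV boundary assigned to BC (E < 50 -> SEY, E >= 50 -> BC); the
# histogram exists for plotting and output, not for the headline numbers.

#' Histogram the emitted-electron energies
#'
#' Half-open uniform bins \[i dE, (i+1) dE) up to `E_max`; energies at or
#' above `E_max` are collected in a terminal overflow bin.
#'
#' @param emitted_energies Numeric vector of emitted energies, eV.
#' @param dE Bin width, eV (> 0).
#' @param E_max Upper edge of the resolved range, eV.
#' @param n_primaries Number of beam primaries, used to normalize the
#'   density column.
#' @return Object of class `emission_spectrum`: a `data.frame` with
#'   columns `E_low`, `E_high`, `counts` and `dY_dE` (electrons per
#'   primary per eV; `NA` for the overflow row), plus attributes
#'   `n_primaries` and `dE`.
#' @export
build_spectrum <- function(emitted_energies, dE = 0.5, E_max = 50,
                           n_primaries = 1) {
  if (!is.finite(dE) || dE <= 0) stop("dE must be > 0", call. = FALSE)
  if (!is.finite(E_max) || E_max <= 0) stop("E_max must be > 0", call. = FALSE)
  nb <- as.integer(ceiling(E_max / dE - 1e-9))  # snap range to whole bins
  E_max <- nb * dE
  edges <- seq(0, E_max, length.out = nb + 1)
  e <- emitted_energies[is.finite(emitted_energies) & emitted_energies >= 0]
  idx <- pmin(floor(e / dE), nb)  # bin nb (0-based) collects the overflow
  counts <- tabulate(idx + 1L, nbins = nb + 1L)
  out <- data.frame(E_low = c(edges[-length(edges)], E_max),
                    E_high = c(edges[-1], Inf),
                    counts = counts,
                    dY_dE = c(counts[seq_len(nb)] / (n_primaries * dE), NA))
  attr(out, "n_primaries") <- n_primaries
  attr(out, "dE") <- dE
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

emitted_records <- function(x) {
  if (inherits(x, "simulation_result")) {
    if (is.null(x$emitted))
      stop("simulation_result was built with keep_emitted = FALSE", call. = FALSE)
    list(energy = x$emitted$energy, primaries = x$n_primaries)
  } else if (is.list(x) && !is.null(x$energy) && !is.null(x$primaries)) {
    list(energy = x$energy, primaries = x$primaries)
  } else {
    stop("expected a simulation_result or list(energy=, primaries=)",
         call. = FALSE)
  }
}

#' Secondary electron yield
#'
#' Emitted electrons with energy below 50 eV per beam primary (the 50 eV
#' boundary itself belongs to the backscattering coefficient).
#'
#' @param result A `simulation_result` or `list(energy =, primaries =)`.
#' @param threshold Boundary energy, eV (default 50).
#' @return The yield, a nonnegative number.
#' @export
compute_sey <- function(result, threshold = 50) {
  r <- emitted_records(result)
  if (r$primaries <= 0) stop("primaries must be > 0", call. = FALSE)
  sum(r$energy < threshold) / r$primaries
}

#' Backscattering coefficient
#'
#' Emitted electrons with energy at or above 50 eV per beam primary.
#'
#' @inheritParams compute_sey
#' @return The coefficient, a nonnegative number.
#' @export
compute_bc <- function(result, threshold = 50) {
  r <- emitted_records(result)
  if (r$primaries <= 0) stop("primaries must be > 0", call. = FALSE)
  sum(r$energy >= threshold) / r$primaries
}

#' Write simulation outputs
#'
#' Writes the spectrum as TSV (`E_low`, `E_high`, `counts`, `dY_dE`) and a
#' JSON summary of all scalar results with a deterministic field order.
#'
#' @param result A `simulation_result`.
#' @param dir Output directory (created if missing).
#' @param basename File stem; writes `<basename>_spectrum.tsv` and
#'   `<basename>_summary.json`.
#' @param config_echo Optional list echoed into the summary for
#'   reproducibility.
#' @param timestamp Include a timestamp field in the summary.
#' @return Invisibly, the two paths (named `spectrum`, `summary`).
#' @export
write_outputs <- function(result, dir, basename = "run", config_echo = NULL,
                          timestamp = TRUE) {
  stopifnot(inherits(result, "simulation_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  spec_path <- file.path(dir, paste0(basename, "_spectrum.tsv"))
  json_path <- file.path(dir, paste0(basename, "_summary.json"))
  utils::write.table(as.data.frame(result$spectrum), spec_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    beam_energy_ev = result$beam_energy,
    n_primaries = result$n_primaries,
    seed = result$seed,
    cutoff_ev = result$cutoff,
    sey = result$sey,
    bc = result$bc,
    counters = result$counters,
    code_version = as.character(utils::packageVersion("seymc")),
    config = config_echo)
  if (timestamp) summary$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(spectrum = spec_path, summary = json_path))
}
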