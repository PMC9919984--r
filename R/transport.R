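# Energy-straggling Monte Carlo: step sampling, process selection, state
# updates, cascade bookkeeping. The per-event inner loop runs in compiled
# code (src/engine.cpp); the R-level operators below are the documented,
# directly testable form of the same collision rules.

#' One electron in flight
#'
#' @param position Numeric length-3 (x, y, z) in m; z >= 0 is inside the
#'   medium.
#' @param direction Unit vector, length 3.
#' @param energy Kinetic energy, eV (>= 0).
#' @param generation 0 for a beam primary, n >= 1 for an n-th generation
#'   secondary.
#' @param id Trajectory id.
#' @return Object of class `electron_state`.
#' @export
electron_state <- function(position = c(0, 0, 0), direction = c(0, 0, 1),
                           energy, generation = 0L, id = 1L) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("direction must be a nonzero vector", call. = FALSE)
  if (abs(nrm - 1) > 1e-12) direction <- direction / nrm
  if (!is.finite(energy) || energy < 0)
    stop("energy must be >= 0", call. = FALSE)
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction),
                 energy = as.numeric(energy),
                 generation = as.integer(generation),
                 id = as.integer(id)),
            class = "electron_state")
}

#' Beam and run configuration
#'
#' @param energy Beam kinetic energy, eV (> 0).
#' @param n_trajectories Number of primary electrons (>= 1).
#' @param seed Integer RNG seed; trajectory `i` uses the independent
#'   stream derived from `seed + i`.
#' @param cutoff Tracking cutoff in eV; electrons below it are counted as
#'   absorbed. `NULL` (default) uses the species' electron affinity.
#' @param direction Incidence direction (default normal incidence, +z).
#' @param max_events Hard cap on collision events per electron.
#' @param grid_points Number of log-spaced energies in the transport
#'   cross-section cache.
#' @param bin_width Spectrum histogram bin width, eV.
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(energy, n_trajectories = 1e4, seed = 1L,
                        cutoff = NULL, direction = c(0, 0, 1),
                        max_events = 1e6, grid_points = 2000,
                        bin_width = 0.5) {
  if (!is.finite(energy) || energy <= 0)
    stop("beam energy must be > 0 (eV)", call. = FALSE)
  if (n_trajectories < 1) stop("n_trajectories must be >= 1", call. = FALSE)
  if (!is.null(cutoff) && cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  structure(list(energy = energy, n_trajectories = as.numeric(n_trajectories),
                 seed = as.numeric(seed), cutoff = cutoff,
                 direction = direction / sqrt(sum(direction^2)),
                 max_events = max_events, grid_points = as.integer(grid_points),
                 bin_width = bin_width),
            class = "beam_config")
}

#' Sample a free-flight step length
#'
#' Delta s = -lambda ln(mu), the inverse transform of the exponential
#' path-length distribution.
#'
#' @param mu Uniform random number(s) in (0, 1\]; exactly 0 is rejected
#'   (logarithmic divergence).
#' @param lambda Mean free path, m (> 0).
#' @return Step length(s) in m.
#' @export
sample_step <- function(mu, lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be > 0", call. = FALSE)
  if (any(mu <= 0) || any(mu > 1))
    stop("mu must lie in (0, 1]; redraw mu = 0", call. = FALSE)
  -lambda * log(mu)
}

#' Select the collision process from the cumulative probabilities
#'
#' Half-open decision intervals: elastic for mu < p1, inelastic
#' (excitation or ionization) for p1 <= mu < p2, phonon for p2 <= mu < p3,
#' polaron for p3 <= mu < 1.
#'
#' @param mu_type Uniform random number(s) in \[0, 1).
#' @param css A [build_cross_section_set()] result.
#' @return Character vector: `"elastic"`, `"inelastic"`, `"phonon"` or
#'   `"polaron"`.
#' @export
select_process <- function(mu_type, css) {
  if (any(mu_type < 0) || any(mu_type >= 1))
    stop("mu_type must lie in [0, 1)", call. = FALSE)
  out <- character(length(mu_type))
  out[mu_type < css$p1] <- "elastic"
  out[mu_type >= css$p1 & mu_type < css$p2] <- "inelastic"
  out[mu_type >= css$p2 & mu_type < css$p3] <- "phonon"
  out[mu_type >= css$p3] <- "polaron"
  out
}

#' Rotate a direction vector by a polar deflection about itself
#'
#' Returns a unit vector at polar angle `theta` from `direction`, with
#' azimuth `phi` measured in the plane orthogonal to `direction`; stable
#' at the +/-z poles.
#'
#' @param direction Unit length-3 vector (nonzero; renormalized).
#' @param theta Polar deflection, radians, in \[0, pi\].
#' @param phi Azimuth, radians, in \[0, 2 pi).
#' @return Unit length-3 vector.
#' @export
rotate_direction <- function(direction, theta, phi) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("direction must be a nonzero vector", call. = FALSE)
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi]", call. = FALSE)
  d <- direction / nrm
  nxy <- sqrt(d[1]^2 + d[2]^2)
  u <- if (nxy > 1e-12) c(-d[2], d[1], 0) / nxy else c(1, 0, 0)
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  out <- cos(theta) * d + sin(theta) * (cos(phi) * u + sin(phi) * v)
  out / sqrt(sum(out^2))
}

#' Apply an inelastic (excitation or ionization) event to an electron
#'
#' Below the ionization threshold the event is an electronic excitation:
#' the state f is sampled with probability sigma_f / sigma_elec and its
#' excitation energy is subtracted. At or above the threshold it is an
#' ionization: the ejected energy W is sampled from the HOMO cumulative,
#' the primary keeps E - W - B_HOMO, and a secondary with kinetic energy W
#' is created at the event position with an isotropic direction.
#'
#' @param state An [electron_state()].
#' @param species A [molecular_species()].
#' @param mu Numeric vector of uniform random numbers; `mu[1]` selects the
#'   excited state or the ejected energy, `mu[2:3]` set the secondary's
#'   direction. Defaults to fresh draws from R's RNG.
#' @return List with elements `primary` (updated state) and `secondary`
#'   (an `electron_state` or `NULL`).
#' @export
apply_inelastic <- function(state, species, mu = runif(3)) {
  E <- state$energy
  if (E < species$ionization_threshold) {
    f <- sample_excited_state(mu[1], E, species)
    state$energy <- E - species$excitation_table$energy_ev[f]
    return(list(primary = state, secondary = NULL))
  }
  homo <- species_homo(species)
  W <- sample_ejected_energy(mu[1], E, species)
  state$energy <- E - W - homo$binding_ev
  stopifnot(state$energy >= 0)  # guaranteed by W <= (E - B)/2
  ct <- 1 - 2 * mu[2]
  st <- sqrt(max(0, 1 - ct^2))
  ph <- 2 * pi * mu[3]
  sec <- electron_state(position = state$position,
                        direction = c(st * cos(ph), st * sin(ph), ct),
                        energy = W, generation = state$generation + 1L,
                        id = state$id)
  list(primary = state, secondary = sec)
}

#' Apply a phonon-creation event to an electron
#'
#' Subtracts the phonon energy and deflects the electron by the angle
#' drawn from [sample_phonon_angle()], with uniform azimuth.
#'
#' @param state An [electron_state()].
#' @param medium A [medium_properties()].
#' @param mu Length-2 uniform random numbers (deflection, azimuth).
#' @return The updated `electron_state`.
#' @export
apply_phonon <- function(state, medium, mu = runif(2)) {
  hw <- medium$phonon_energy
  if (state$energy <= hw)
    stop("phonon channel closed at this energy", call. = FALSE)
  Ep <- state$energy - hw
  theta <- sample_phonon_angle(mu[1], state$energy, Ep)
  state$direction <- rotate_direction(state$direction, theta, 2 * pi * mu[2])
  state$energy <- Ep
  state
}

#' Apply a polaron-trapping event
#'
#' The electron is removed from the simulation and counted as trapped.
#'
#' @param state An [electron_state()].
#' @return The state with `energy` untouched and attribute
#'   `status = "trapped"`.
#' @export
apply_polaron <- function(state) {
  attr(state, "status") <- "trapped"
  state
}

#' Run a single primary trajectory (with its full cascade)
#'
#' Convenience wrapper around the compiled engine for one primary, with
#' the per-event trace enabled.
#'
#' @param beam A [beam_config()] (its `n_trajectories` is ignored).
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @return `data.frame` of emitted electrons (`energy`, `generation`) with
#'   attributes `trace` (per-event `data.frame`), `counters` and
#'   `residual` (cascade energy-balance error, eV).
#' @export
run_trajectory <- function(beam, species, medium) {
  b <- beam
  b$n_trajectories <- 1
  res <- run_simulation(b, species, medium, trace = TRUE, residuals = TRUE)
  out <- res$emitted
  attr(out, "trace") <- res$trace
  attr(out, "counters") <- res$counters
  attr(out, "residual") <- res$residuals[1]
  out
}

#' Run a full Monte Carlo simulation at one beam energy
#'
#' Transports `beam$n_trajectories` primaries (normal incidence on the
#' z = 0 surface of a semi-infinite homogeneous slab) and all their
#' secondaries until emission through the surface, polaron trapping, or
#' fall-off below the tracking cutoff. Fully reproducible for a given
#' seed.
#'
#' @param beam A [beam_config()].
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @param trace Record a per-event trace (tiny runs only).
#' @param residuals Return the per-trajectory energy-balance residuals.
#' @param keep_emitted Keep the individual emitted-electron records.
#' @return Object of class `simulation_result`: beam energy, SEY `sey`,
#'   backscattering coefficient `bc`, `spectrum` (see [build_spectrum()]),
#'   `counters`, `emitted`, `seed`, `n_primaries`.
#' @export
run_simulation <- function(beam, species, medium, trace = FALSE,
                           residuals = FALSE, keep_emitted = TRUE) {
  stopifnot(inherits(beam, "beam_config"))
  validate_species(species)
  validate_medium(medium)
  # a beam below the cutoff is legal: primaries are absorbed immediately
  cutoff <- if (is.null(beam$cutoff)) species$electron_affinity else beam$cutoff
  pars <- engine_pars(species, medium)
  eng <- run_engine_cpp(pars, beam$energy, beam$n_trajectories, beam$seed,
                        cutoff, beam$max_events, beam$grid_points,
                        trace, residuals, 2e6)
  emitted <- data.frame(energy = eng$emitted_energy,
                        generation = eng$emitted_generation)
  spec <- build_spectrum(emitted$energy, dE = beam$bin_width, E_max = 50,
                         n_primaries = beam$n_trajectories)
  res <- structure(list(
    beam_energy = beam$energy,
    n_primaries = beam$n_trajectories,
    seed = beam$seed,
    cutoff = cutoff,
    sey = sum(emitted$energy < 50) / beam$n_trajectories,
    bc = sum(emitted$energy >= 50) / beam$n_trajectories,
    spectrum = spec,
    counters = eng$counters,
    emitted = if (keep_emitted) emitted else NULL),
    class = "simulation_result")
  if (residuals) res$residuals <- eng$residuals
  if (trace) res$trace <- eng$trace
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> E_beam = %.4g eV, %g primaries (seed %g)\n",
              x$beam_energy, x$n_primaries, x$seed))
  cat(sprintf("  SEY = %.4f, BC = %.4f (cutoff %.3f eV)\n", x$sey, x$bc,
              x$cutoff))
  ct <- x$counters
  cat(sprintf("  emitted %g, trapped %g, absorbed %g, secondaries %g, events %g\n",
              ct$emitted, ct$trapped, ct$absorbed, ct$secondaries_created,
              ct$total_events))
  invisible(x)
}

#' Sweep the beam energy
#'
#' Runs [run_simulation()] on a grid of beam energies with matched
#' per-energy seeds and collects SEY and BC.
#'
#' @param beam_energies Beam energies, eV.
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @param n_trajectories,seed,... Passed to [beam_config()].
#' @return `data.frame` with columns `E_beam_eV`, `sey`, `bc`,
#'   `sey_se`, `bc_se` (binomial-style standard errors), `emitted`,
#'   `trapped`.
#' @export
sweep_beam_energy <- function(beam_energies, species, medium,
                              n_trajectories = 1e4, seed = 1L, ...) {
  rows <- lapply(beam_energies, function(E) {
    res <- run_simulation(beam_config(E, n_trajectories, seed, ...),
                          species, medium, keep_emitted = TRUE)
    n <- res$n_primaries
    data.frame(E_beam_eV = E, sey = res$sey, bc = res$bc,
               sey_se = sqrt(res$sey / n), bc_se = sqrt(res$bc / n),
               emitted = res$counters$emitted,
               trapped = res$counters$trapped)
  })
  do.call(rbind, rows)
}
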