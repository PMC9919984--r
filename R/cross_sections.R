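# Channel cross sections, their differential/cumulative forms and
# inverse-transform samplers. The closed forms are evaluated in compiled
# code (src/xsections.h); these wrappers add validation and unit handling.

species_elastic_pars <- function(species) {
  pc <- physical_constants()
  list(d2 = (species$dipole_components * pc$debye_au)^2,
       dw = rotational_quantum(species$rotational_constants))
}

species_excitation_pars <- function(species) {
  pc <- physical_constants()
  et <- species$excitation_table
  list(d2 = as.numeric((et$transition_dipole_debye * pc$debye_au)^2),
       dw = as.numeric(et$energy_ev))
}

species_homo <- function(species) {
  ot <- species$orbital_table
  ot[which.min(ot$binding_ev), , drop = FALSE]
}

check_energy <- function(E) {
  if (any(!is.finite(E)) || any(E <= 0))
    stop("collision energy E must be finite and > 0 (eV)", call. = FALSE)
}

#' Elastic (rotational dipole) cross section
#'
#' First-Born charge--dipole cross section summed over the three principal
#' inertia axes: sigma_d = (8 pi / 3 k^2) D_d^2 ln[(k + k_d)/(k - k_d)],
#' where k_d is the wavenumber after exciting the axis's rotational quantum
#' 2 h B_d. An axis contributes zero when its dipole component vanishes or
#' the channel is closed (E <= 2 h B_d).
#'
#' @param E Collision energy in eV (> 0); vectorized.
#' @param species A [molecular_species()].
#' @return Cross section in m^2.
#' @examples
#' sigma_elastic(1000, maa_conformer("CC"))
#' @export
sigma_elastic <- function(E, species) {
  check_energy(E)
  p <- species_elastic_pars(species)
  xs_dipole_total_cpp(as.numeric(E), p$d2, p$dw)
}

#' Differential elastic cross section
#'
#' Per-axis form (4 D_d^2 / 3)(k_d / k) / (k^2 + k_d^2 - 2 k k_d cos theta),
#' summed over axes; its solid-angle integral reproduces [sigma_elastic()].
#'
#' @param theta Polar scattering angle(s) in radians, within \[0, pi\].
#' @param E Collision energy, eV.
#' @param species A [molecular_species()].
#' @return Differential cross section in m^2/sr.
#' @export
dcs_elastic <- function(theta, E, species) {
  check_energy(E)
  if (any(theta < 0) || any(theta > pi))
    stop("theta must lie in [0, pi]", call. = FALSE)
  p <- species_elastic_pars(species)
  dcs_dipole_cpp(as.numeric(theta), E, p$d2, p$dw)
}

#' Cumulative probability of the elastic scattering angle
#'
#' Normalized integral of [dcs_elastic()] over solid angle from 0 to theta;
#' closed form proportional to
#' sum_d D_d^2 ln\[(k^2 + k_d^2 - 2 k k_d cos theta) / (k - k_d)^2\].
#' Monotone from 0 at theta = 0 to 1 at theta = pi.
#'
#' @inheritParams dcs_elastic
#' @return Probability in \[0, 1\].
#' @export
cumulative_elastic <- function(theta, E, species) {
  check_energy(E)
  if (any(theta < 0) || any(theta > pi))
    stop("theta must lie in [0, pi]", call. = FALSE)
  p <- species_elastic_pars(species)
  cum_dipole_cpp(as.numeric(theta), E, p$d2, p$dw)
}

#' Sample the elastic scattering angle by inverse transform
#'
#' Solves cumulative_elastic(theta) = mu by bisection on log(1 - cos theta)
#' (the distribution is extremely forward peaked at keV energies), to a
#' residual below 1e-12 in the cumulative.
#'
#' @param mu Uniform random number(s) in \[0, 1\].
#' @param E Collision energy, eV.
#' @param species A [molecular_species()].
#' @return Polar angle theta in radians.
#' @export
sample_elastic_angle <- function(mu, E, species) {
  check_energy(E)
  p <- species_elastic_pars(species)
  sample_dipole_angle_cpp(as.numeric(mu), E, p$d2, p$dw)
}

#' Electronic excitation cross section
#'
#' First Born approximation driven by transition dipole moments: the same
#' closed form as the elastic channel with (D_0f, Delta E_0f) per excited
#' state; a state contributes zero below its threshold.
#'
#' @param E Collision energy in eV (> 0); vectorized.
#' @param species A [molecular_species()].
#' @return Total excitation cross section in m^2.
#' @seealso [sigma_excitation_states()] for the per-state breakdown.
#' @export
sigma_excitation <- function(E, species) {
  check_energy(E)
  p <- species_excitation_pars(species)
  if (length(p$d2) == 0) return(rep(0, length(E)))
  xs_dipole_total_cpp(as.numeric(E), p$d2, p$dw)
}

#' Per-state breakdown of the excitation cross section
#'
#' @param E Single collision energy, eV.
#' @param species A [molecular_species()].
#' @return `data.frame` with columns `state`, `energy_ev`, `sigma_m2`.
#' @export
sigma_excitation_states <- function(E, species) {
  check_energy(E)
  stopifnot(length(E) == 1)
  p <- species_excitation_pars(species)
  data.frame(state = seq_along(p$d2), energy_ev = p$dw,
             sigma_m2 = if (length(p$d2)) xs_dipole_terms_cpp(E, p$d2, p$dw)
                        else numeric(0))
}

#' Sample the excited state reached in an excitation event
#'
#' State f is drawn with probability sigma_f / sigma_elec among the open
#' states at energy E.
#'
#' @param mu Uniform random number in \[0, 1).
#' @param E Collision energy, eV.
#' @param species A [molecular_species()].
#' @return Integer row index into `species$excitation_table`.
#' @export
sample_excited_state <- function(mu, E, species) {
  check_energy(E)
  stopifnot(length(mu) == 1, mu >= 0, mu <= 1)
  s <- sigma_excitation_states(E, species)$sigma_m2
  tot <- sum(s)
  if (!length(s) || tot <= 0)
    stop("no open excitation channel at this energy", call. = FALSE)
  cum <- cumsum(s) / tot
  idx <- findInterval(mu, cum, left.open = FALSE) + 1L
  min(idx, length(s))
}

#' Binary-Encounter-Bethe cross section for one orbital
#'
#' sigma_i = S_i/(t + u + 1) \[(2 - Q)(1 - 1/t - ln t/(t + 1)) +
#' (Q ln t / 2)(1 - 1/t^2)\] with t = E/B_i, u = U_i/B_i and
#' S_i = 4 pi a0^2 N_i (R/B_i)^2; zero at and below t = 1.
#'
#' @param E Collision energy in eV; vectorized.
#' @param orbital One-row `data.frame` (or list) with `binding_ev`,
#'   `kinetic_ev`, `occupation`, `q`.
#' @return Cross section in m^2.
#' @export
sigma_beb_orbital <- function(E, orbital) {
  check_energy(E)
  xs_beb_cpp(as.numeric(E), orbital$binding_ev, orbital$kinetic_ev,
             orbital$occupation, orbital$q)
}

#' Total ionization cross section (BEB, summed over occupied orbitals)
#'
#' @param E Collision energy in eV; vectorized.
#' @param species A [molecular_species()].
#' @return Cross section in m^2; zero at and below the HOMO binding energy.
#' @export
sigma_ionization <- function(E, species) {
  check_energy(E)
  ot <- species$orbital_table
  xs_ionization_cpp(as.numeric(E), ot$binding_ev, ot$kinetic_ev,
                    ot$occupation, ot$q)
}

#' Cumulative probability of the ejected-electron energy (BEB)
#'
#' Closed-form integral of the BEB singly-differential cross section from 0
#' to W, normalized by the orbital cross section; monotone from 0 at W = 0
#' to 1 at W = (E - B)/2.
#'
#' @param W Ejected energy(ies), eV, within \[0, (E - B)/2\].
#' @param E Collision energy, eV; must exceed the orbital binding energy.
#' @param orbital Orbital row as in [sigma_beb_orbital()].
#' @return Probability in \[0, 1\].
#' @export
cumulative_beb <- function(W, E, orbital) {
  check_energy(E)
  B <- orbital$binding_ev
  if (E <= B) stop("E must exceed the orbital binding energy", call. = FALSE)
  wmax <- (E - B) / 2
  if (any(W < 0) || any(W > wmax * (1 + 1e-12)))
    stop(sprintf("W must lie in [0, %.6g] eV", wmax), call. = FALSE)
  cum_beb_cpp(pmin(as.numeric(W), wmax), E, B, orbital$q)
}

#' Sample the ejected-electron energy of an ionization event
#'
#' Inverts the HOMO cumulative by bisection on W in \[0, (E - B_HOMO)/2\].
#'
#' @param mu Uniform random number(s) in \[0, 1\].
#' @param E Collision energy, eV; must exceed the HOMO binding energy.
#' @param species A [molecular_species()].
#' @return Ejected energy W in eV.
#' @export
sample_ejected_energy <- function(mu, E, species) {
  check_energy(E)
  homo <- species_homo(species)
  if (E <= homo$binding_ev)
    stop("E must exceed the HOMO binding energy", call. = FALSE)
  sample_beb_cpp(as.numeric(mu), E, homo$binding_ev, homo$q)
}

#' Electron--phonon (Froehlich) cross section
#'
#' Longitudinal optical phonon creation in a polarizable medium:
#' sigma = (1/N)(1/a0) (n(T)+1)/2 (eps0 - epsinf)/(eps0 epsinf)
#' (hw/E) ln\[(1 + sqrt(1 - hw/E)) / (1 - sqrt(1 - hw/E))\];
#' zero at and below the phonon energy.
#'
#' @param E Electron energy in eV; vectorized.
#' @param medium A [medium_properties()].
#' @return Cross section in m^2.
#' @export
sigma_phonon <- function(E, medium) {
  check_energy(E)
  xs_phonon_cpp(as.numeric(E), medium$number_density, medium$phonon_energy,
                medium$eps_static, medium$eps_highfreq, medium$temperature)
}

#' Sample the deflection angle of a phonon-creation event
#'
#' cos theta' = ((E + E')/(2 sqrt(E E')))(1 - B^mu) + B^mu with
#' B = (E + E' + 2 sqrt(E E'))/(E + E' - 2 sqrt(E E')); exact endpoints
#' theta' = 0 at mu = 0 and theta' = pi at mu = 1, monotone in mu.
#'
#' @param mu Uniform random number(s) in \[0, 1\].
#' @param E Energy before the collision, eV.
#' @param Eprime Energy after the collision (E - phonon energy), eV; must
#'   satisfy 0 < Eprime < E.
#' @return Deflection angle theta' in radians.
#' @export
sample_phonon_angle <- function(mu, E, Eprime) {
  if (!is.finite(Eprime) || Eprime <= 0 || Eprime >= E)
    stop("Eprime must satisfy 0 < Eprime < E", call. = FALSE)
  acos(phonon_costheta_cpp(as.numeric(mu), E, Eprime))
}

#' Polaron trapping cross section (Ganachaud--Mokrani)
#'
#' sigma = (S_trap / N) exp(-gamma_trap E).
#'
#' @param E Electron energy in eV (>= 0); vectorized.
#' @param medium A [medium_properties()].
#' @return Cross section in m^2.
#' @export
sigma_polaron <- function(E, medium) {
  if (any(!is.finite(E)) || any(E < 0))
    stop("E must be finite and >= 0 (eV)", call. = FALSE)
  xs_polaron_cpp(as.numeric(E), medium$number_density, medium$trap_strength,
                 medium$trap_exponent)
}

#' All channel cross sections, process probabilities and mean free path
#'
#' Evaluates the five channels at one energy, the total cross section
#' (their sum), the total mean free path lambda = 1/(N sigma_tot), and the
#' cumulative process-selection probabilities p1 (elastic), p2 (+
#' electronic excitation and ionization), p3 (+ phonon), p4 = 1 (polaron).
#'
#' @param E Single collision energy, eV.
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @return Object of class `cross_section_set`.
#' @export
build_cross_section_set <- function(E, species, medium) {
  check_energy(E)
  stopifnot(length(E) == 1)
  s <- c(el = sigma_elastic(E, species),
         elec = sigma_excitation(E, species),
         ion = sigma_ionization(E, species),
         phonon = sigma_phonon(E, medium),
         polaron = sigma_polaron(E, medium))
  tot <- sum(s)
  if (tot <= 0)
    stop("total cross section is zero at this energy", call. = FALSE)
  structure(list(
    energy = E,
    sigma_el = s[["el"]], sigma_elec = s[["elec"]], sigma_ion = s[["ion"]],
    sigma_phonon = s[["phonon"]], sigma_polaron = s[["polaron"]],
    sigma_total = tot,
    lambda_total = 1 / (medium$number_density * tot),
    p1 = s[["el"]] / tot,
    p2 = (s[["el"]] + s[["elec"]] + s[["ion"]]) / tot,
    p3 = (s[["el"]] + s[["elec"]] + s[["ion"]] + s[["phonon"]]) / tot,
    p4 = 1), class = "cross_section_set")
}

#' @export
print.cross_section_set <- function(x, ...) {
  cat(sprintf("<cross_section_set> E = %.4g eV\n", x$energy))
  cat(sprintf("  el %.3e  elec %.3e  ion %.3e  phonon %.3e  polaron %.3e m^2\n",
              x$sigma_el, x$sigma_elec, x$sigma_ion, x$sigma_phonon,
              x$sigma_polaron))
  cat(sprintf("  total %.3e m^2, lambda %.3e m, p = (%.4f, %.4f, %.4f, 1)\n",
              x$sigma_total, x$lambda_total, x$p1, x$p2, x$p3))
  invisible(x)
}

#' Inelastic mean free path
#'
#' lambda_inel = 1 / (N (sigma_elec + sigma_ion)); `Inf` where both
#' electronic channels are closed.
#'
#' @param E Collision energy in eV; vectorized.
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @return Mean free path in m.
#' @export
inelastic_mean_free_path <- function(E, species, medium) {
  check_energy(E)
  s <- sigma_excitation(E, species) + sigma_ionization(E, species)
  out <- rep(Inf, length(s))
  open <- s > 0
  out[open] <- 1 / (medium$number_density * s[open])
  out
}

#' Per-energy cross-section table
#'
#' Evaluates every channel on an energy grid; the column layout matches the
#' TSV dump written by [cmd_xsec()].
#'
#' @param E Energy grid, eV.
#' @param species A [molecular_species()].
#' @param medium A [medium_properties()].
#' @return `data.frame` with columns `E_eV`, `sigma_el_m2`, `sigma_elec_m2`,
#'   `sigma_ion_m2`, `sigma_phonon_m2`, `sigma_polaron_m2`, `sigma_tot_m2`,
#'   `imfp_m`.
#' @export
cross_section_table <- function(E, species, medium) {
  check_energy(E)
  el <- sigma_elastic(E, species)
  elec <- sigma_excitation(E, species)
  ion <- sigma_ionization(E, species)
  ph <- sigma_phonon(E, medium)
  pol <- sigma_polaron(E, medium)
  data.frame(E_eV = E, sigma_el_m2 = el, sigma_elec_m2 = elec,
             sigma_ion_m2 = ion, sigma_phonon_m2 = ph,
             sigma_polaron_m2 = pol,
             sigma_tot_m2 = el + elec + ion + ph + pol,
             imfp_m = inelastic_mean_free_path(E, species, medium))
}
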