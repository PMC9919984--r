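#' Construct a molecular species
#'
#' Bundles every per-molecule parameter the five collision channels need.
#' All energies are in eV, dipoles in Debye and rotational constants in GHz;
#' conversion to the internal unit system (eV, m, atomic-unit dipoles)
#' happens once, inside the cross-section layer.
#'
#' @param name Species label, e.g. `"CC"`.
#' @param dipole_components Numeric length-3, permanent dipole moment
#'   components along the principal inertia axes, Debye. Signs are
#'   irrelevant for the cross sections (they enter squared).
#' @param rotational_constants Numeric length-3, rotational constants for
#'   the same axes, GHz. All must be positive.
#' @param orbital_table `data.frame` with columns `binding_ev` (B_i > 0),
#'   `kinetic_ev` (U_i > 0, mean kinetic energy of the bound electron),
#'   `occupation` (N_i, integer >= 1) and `q` (BEB oscillator parameter,
#'   in (0, 2]; 1 when oscillator strengths are unknown). The orbital with
#'   the smallest binding energy is the HOMO and must match
#'   `ionization_threshold`.
#' @param excitation_table `data.frame` with columns `energy_ev`
#'   (excitation energy, > 0) and `transition_dipole_debye`. May have zero
#'   rows (excitation channel inactive).
#' @param ionization_threshold Positive magnitude of the ionization
#'   threshold, eV.
#' @param electron_affinity Electron affinity, eV (>= 0); default transport
#'   cutoff.
#' @param gap_energy Energy of the lowest intense electronic excitation, eV.
#' @param homo_tolerance Allowed |B_HOMO - ionization_threshold| in eV.
#' @return Validated object of class `molecular_species`.
#' @seealso [load_species()], [maa_conformer()], [make_toy_species()]
#' @export
molecular_species <- function(name, dipole_components, rotational_constants,
                              orbital_table, excitation_table = NULL,
                              ionization_threshold, electron_affinity,
                              gap_energy, homo_tolerance = 0.01) {
  if (is.null(excitation_table)) {
    excitation_table <- data.frame(energy_ev = numeric(0),
                                   transition_dipole_debye = numeric(0))
  }
  sp <- structure(
    list(name = as.character(name),
         dipole_components = as.numeric(dipole_components),
         rotational_constants = as.numeric(rotational_constants),
         orbital_table = as.data.frame(orbital_table),
         excitation_table = as.data.frame(excitation_table),
         ionization_threshold = as.numeric(ionization_threshold),
         electron_affinity = as.numeric(electron_affinity),
         gap_energy = as.numeric(gap_energy)),
    class = "molecular_species")
  validate_species(sp, homo_tolerance = homo_tolerance)
}

#' Validate a molecular species
#'
#' Enforces every structural invariant; errors name the offending field.
#'
#' @param species Object of class `molecular_species`.
#' @param homo_tolerance Allowed |B_HOMO - ionization_threshold| in eV.
#' @return The species, invisibly unchanged, if valid.
#' @export
validate_species <- function(species, homo_tolerance = 0.01) {
  sp <- species
  fail <- function(field, msg) {
    stop(sprintf("invalid species '%s': field '%s' %s",
                 if (length(sp$name)) sp$name else "?", field, msg),
         call. = FALSE)
  }
  required <- c("name", "dipole_components", "rotational_constants",
                "orbital_table", "excitation_table", "ionization_threshold",
                "electron_affinity", "gap_energy")
  for (f in required) {
    if (is.null(sp[[f]])) fail(f, "is missing")
  }
  if (length(sp$dipole_components) != 3 || anyNA(sp$dipole_components))
    fail("dipole_components", "must be three finite values (Debye)")
  if (length(sp$rotational_constants) != 3 || anyNA(sp$rotational_constants))
    fail("rotational_constants", "must be three finite values (GHz)")
  if (any(sp$rotational_constants <= 0))
    fail("rotational_constants", "must all be > 0")
  ot <- sp$orbital_table
  cols <- c("binding_ev", "kinetic_ev", "occupation", "q")
  if (nrow(ot) < 1) fail("orbital_table", "must contain at least one orbital")
  if (!all(cols %in% names(ot)))
    fail("orbital_table", paste("needs columns", paste(cols, collapse = ", ")))
  if (any(ot$binding_ev <= 0)) fail("orbital_table$binding_ev", "must be > 0")
  if (any(ot$kinetic_ev <= 0)) fail("orbital_table$kinetic_ev", "must be > 0")
  if (any(ot$occupation < 1) || any(ot$occupation != round(ot$occupation)))
    fail("orbital_table$occupation", "must be integers >= 1")
  if (any(ot$q <= 0) || any(ot$q > 2)) fail("orbital_table$q", "must lie in (0, 2]")
  et <- sp$excitation_table
  if (nrow(et) > 0) {
    if (!all(c("energy_ev", "transition_dipole_debye") %in% names(et)))
      fail("excitation_table",
           "needs columns energy_ev, transition_dipole_debye")
    if (any(et$energy_ev <= 0)) fail("excitation_table$energy_ev", "must be > 0")
  }
  if (!is.finite(sp$ionization_threshold) || sp$ionization_threshold <= 0)
    fail("ionization_threshold", "must be a positive magnitude (eV)")
  if (!is.finite(sp$electron_affinity) || sp$electron_affinity < 0)
    fail("electron_affinity", "must be >= 0")
  if (!is.finite(sp$gap_energy) || sp$gap_energy <= 0)
    fail("gap_energy", "must be > 0")
  b_homo <- min(ot$binding_ev)
  if (abs(b_homo - sp$ionization_threshold) > homo_tolerance)
    fail("orbital_table",
         sprintf("HOMO binding energy %.4f eV does not match ionization_threshold %.4f eV",
                 b_homo, sp$ionization_threshold))
  invisible(sp)
}

#' @export
print.molecular_species <- function(x, ...) {
  cat(sprintf("<molecular_species> %s\n", x$name))
  cat(sprintf("  |D| = %.3f Debye  (components %s)\n", dipole_magnitude(x),
              paste(sprintf("%.2f", x$dipole_components), collapse = ", ")))
  cat(sprintf("  B_d = %s GHz\n",
              paste(sprintf("%.2f", x$rotational_constants), collapse = ", ")))
  cat(sprintf("  %d orbitals (HOMO %.3f eV), %d excited states, E_ion %.3f eV, E_EA %.3f eV, E_gap %.2f eV\n",
              nrow(x$orbital_table), min(x$orbital_table$binding_ev),
              nrow(x$excitation_table), x$ionization_threshold,
              x$electron_affinity, x$gap_energy))
  invisible(x)
}

#' Construct bulk medium properties
#'
#' @param number_density Molecules per cubic metre (> 0).
#' @param phonon_energy Longitudinal optical phonon energy, eV (> 0).
#' @param eps_static Static dielectric constant, must exceed `eps_highfreq`.
#' @param eps_highfreq High-frequency dielectric constant (> 0).
#' @param temperature Temperature, K (> 0).
#' @param trap_strength Polaron trap strength S_trap, 1/m (>= 0).
#' @param trap_exponent Polaron trap exponent gamma_trap, 1/eV (>= 0).
#' @return Object of class `medium_properties`.
#' @export
medium_properties <- function(number_density, phonon_energy, eps_static,
                              eps_highfreq, temperature, trap_strength,
                              trap_exponent) {
  md <- structure(
    list(number_density = as.numeric(number_density),
         phonon_energy = as.numeric(phonon_energy),
         eps_static = as.numeric(eps_static),
         eps_highfreq = as.numeric(eps_highfreq),
         temperature = as.numeric(temperature),
         trap_strength = as.numeric(trap_strength),
         trap_exponent = as.numeric(trap_exponent)),
    class = "medium_properties")
  validate_medium(md)
}

#' Validate medium properties
#' @param medium Object of class `medium_properties`.
#' @return The medium, invisibly, if valid.
#' @export
validate_medium <- function(medium) {
  fail <- function(field, msg) {
    stop(sprintf("invalid medium: field '%s' %s", field, msg), call. = FALSE)
  }
  chk <- function(field, ok) if (!isTRUE(ok)) fail(field, "fails its constraint")
  if (!is.finite(medium$number_density) || medium$number_density <= 0)
    fail("number_density", "must be > 0 (molecules per m^3)")
  if (!is.finite(medium$phonon_energy) || medium$phonon_energy <= 0)
    fail("phonon_energy", "must be > 0 (eV)")
  if (!is.finite(medium$eps_highfreq) || medium$eps_highfreq <= 0)
    fail("eps_highfreq", "must be > 0")
  if (!is.finite(medium$eps_static) || medium$eps_static <= medium$eps_highfreq)
    fail("eps_static", "must exceed eps_highfreq")
  if (!is.finite(medium$temperature) || medium$temperature <= 0)
    fail("temperature", "must be > 0 (K)")
  if (!is.finite(medium$trap_strength) || medium$trap_strength < 0)
    fail("trap_strength", "must be >= 0 (1/m)")
  if (!is.finite(medium$trap_exponent) || medium$trap_exponent < 0)
    fail("trap_exponent", "must be >= 0 (1/eV)")
  invisible(medium)
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("<medium_properties>\n")
  cat(sprintf("  N = %.3e m^-3, phonon %.3f eV, eps(0)/eps(inf) = %.2f/%.2f, T = %.1f K\n",
              x$number_density, x$phonon_energy, x$eps_static, x$eps_highfreq,
              x$temperature))
  cat(sprintf("  polaron: S_trap = %.3e 1/m, gamma_trap = %.3f 1/eV\n",
              x$trap_strength, x$trap_exponent))
  invisible(x)
}

# --- configuration I/O -------------------------------------------------------

species_from_list <- function(x, homo_tolerance = 0.01) {
  need <- function(key) {
    if (is.null(x[[key]])) {
      stop(sprintf("species config: field '%s' is missing", key), call. = FALSE)
    }
    x[[key]]
  }
  orb <- need("orbitals")
  if (length(orb) == 0) stop("species config: field 'orbitals' is empty", call. = FALSE)
  orbital_table <- do.call(rbind, lapply(orb, function(o) {
    data.frame(binding_ev = as.numeric(o$binding_ev),
               kinetic_ev = as.numeric(o$kinetic_ev),
               occupation = as.numeric(o$occupation),
               q = as.numeric(if (is.null(o$q)) 1 else o$q))
  }))
  exc <- x$excitations
  excitation_table <- if (length(exc) == 0) NULL else do.call(rbind, lapply(exc, function(e) {
    data.frame(energy_ev = as.numeric(e$energy_ev),
               transition_dipole_debye = as.numeric(e$transition_dipole_debye))
  }))
  molecular_species(
    name = need("name"),
    dipole_components = as.numeric(need("dipole_components_debye")),
    rotational_constants = as.numeric(need("rotational_constants_ghz")),
    orbital_table = orbital_table,
    excitation_table = excitation_table,
    ionization_threshold = abs(as.numeric(need("ionization_threshold_ev"))),
    electron_affinity = abs(as.numeric(need("electron_affinity_ev"))),
    gap_energy = as.numeric(need("gap_energy_ev")),
    homo_tolerance = homo_tolerance)
}

medium_from_list <- function(x) {
  need <- function(key) {
    if (is.null(x[[key]])) {
      stop(sprintf("medium config: field '%s' is missing", key), call. = FALSE)
    }
    as.numeric(x[[key]])
  }
  medium_properties(
    number_density = need("number_density_m3"),
    phonon_energy = need("phonon_energy_ev"),
    eps_static = need("eps_static"),
    eps_highfreq = need("eps_highfreq"),
    temperature = need("temperature_k"),
    trap_strength = need("trap_strength_m1"),
    trap_exponent = need("trap_exponent_ev1"))
}

#' Load a molecular species from a YAML configuration
#'
#' The configuration may be a file path, a YAML string, or an already-parsed
#' list. A top-level `species:` block is accepted; otherwise the mapping
#' itself is taken as the species block. Key names are case-sensitive and
#' listed in the package README. `ionization_threshold_ev` and
#' `electron_affinity_ev` are stored as positive magnitudes regardless of
#' the sign convention used in the file.
#'
#' @param config_source Path, YAML string, or list.
#' @param homo_tolerance Allowed |B_HOMO - ionization_threshold|, eV.
#' @return A validated [molecular_species()].
#' @export
load_species <- function(config_source, homo_tolerance = 0.01) {
  x <- parse_config_source(config_source)
  if (!is.null(x$species)) x <- x$species
  species_from_list(x, homo_tolerance = homo_tolerance)
}

#' Load medium properties from a YAML configuration
#' @inheritParams load_species
#' @return A validated [medium_properties()].
#' @export
load_medium <- function(config_source) {
  x <- parse_config_source(config_source)
  if (!is.null(x$medium)) x <- x$medium
  medium_from_list(x)
}

#' Load a full run configuration (species, medium, beam, output blocks)
#'
#' @param config_source Path, YAML string, or list with blocks `species`,
#'   `medium` and optionally `beam` and `output`.
#' @return List with elements `species`, `medium`, `beam` (list or NULL)
#'   and `output` (list or NULL).
#' @export
load_config <- function(config_source) {
  x <- parse_config_source(config_source)
  if (is.null(x$species)) stop("config: block 'species' is missing", call. = FALSE)
  if (is.null(x$medium)) stop("config: block 'medium' is missing", call. = FALSE)
  list(species = species_from_list(x$species),
       medium = medium_from_list(x$medium),
       beam = x$beam,
       output = x$output)
}

parse_config_source <- function(config_source) {
  if (is.list(config_source)) return(config_source)
  if (!is.character(config_source) || length(config_source) != 1)
    stop("config source must be a file path, YAML string, or list", call. = FALSE)
  if (file.exists(config_source)) {
    yaml::read_yaml(config_source)
  } else {
    yaml::yaml.load(config_source)
  }
}

#' Serialize a species (and optionally a medium) back to a config list
#'
#' Inverse of [load_species()]: `load_species(species_to_config(x))`
#' reconstructs an identical species.
#'
#' @param species A `molecular_species`.
#' @param medium Optional `medium_properties` to embed as a `medium` block.
#' @return A list mirroring the YAML layout.
#' @export
species_to_config <- function(species, medium = NULL) {
  ot <- species$orbital_table
  et <- species$excitation_table
  out <- list(species = list(
    name = species$name,
    dipole_components_debye = species$dipole_components,
    rotational_constants_ghz = species$rotational_constants,
    ionization_threshold_ev = species$ionization_threshold,
    electron_affinity_ev = species$electron_affinity,
    gap_energy_ev = species$gap_energy,
    orbitals = lapply(seq_len(nrow(ot)), function(i) {
      list(binding_ev = ot$binding_ev[i], kinetic_ev = ot$kinetic_ev[i],
           occupation = ot$occupation[i], q = ot$q[i])
    }),
    excitations = lapply(seq_len(nrow(et)), function(i) {
      list(energy_ev = et$energy_ev[i],
           transition_dipole_debye = et$transition_dipole_debye[i])
    })))
  if (!is.null(medium)) {
    out$medium <- list(
      number_density_m3 = medium$number_density,
      phonon_energy_ev = medium$phonon_energy,
      eps_static = medium$eps_static,
      eps_highfreq = medium$eps_highfreq,
      temperature_k = medium$temperature,
      trap_strength_m1 = medium$trap_strength,
      trap_exponent_ev1 = medium$trap_exponent)
  }
  out
}

#' Bundled methacrylic acid conformer fixtures
#'
#' Loads one of the four MAA conformers (cis-chain `CC`, cis-ring `CR`,
#' trans-chain `TC`, trans-ring `TR`). Dipole components, rotational
#' constants, ionization threshold, electron affinity and gap energy are
#' the published quantum-chemistry values for these conformers; the orbital
#' and excitation tables and the accompanying medium block are documented
#' placeholders (see the fixture files and the methods vignette).
#'
#' @param name One of `"CC"`, `"CR"`, `"TC"`, `"TR"`.
#' @return A validated [molecular_species()].
#' @examples
#' cc <- maa_conformer("CC")
#' dipole_magnitude(cc)
#' @export
maa_conformer <- function(name = c("CC", "CR", "TC", "TR")) {
  name <- match.arg(toupper(name), c("CC", "CR", "TC", "TR"))
  path <- system.file("extdata", paste0("maa_", tolower(name), ".yaml"),
                      package = "seymc", mustWork = TRUE)
  load_species(path)
}

#' Placeholder gel medium bundled with the MAA fixtures
#'
#' The bulk parameters of the MAA gel are not part of the published
#' molecular data; this medium block is an assumed, literature-typical
#' parameterization for a polar organic insulator (see the methods
#' vignette) and is shared by all four conformer fixtures.
#'
#' @return A validated [medium_properties()].
#' @export
maa_medium <- function() {
  path <- system.file("extdata", "maa_cc.yaml", package = "seymc",
                      mustWork = TRUE)
  load_medium(path)
}

#' Euclidean magnitude of the permanent dipole moment
#'
#' @param species A `molecular_species`.
#' @return Dipole magnitude in Debye.
#' @examples
#' dipole_magnitude(maa_conformer("TR"))
#' @export
dipole_magnitude <- function(species) {
  sqrt(sum(species$dipole_components^2))
}

#' Rotational excitation quantum for one inertia axis
#'
#' The energy difference between the two lowest rotational levels of the
#' axis, 2 h B_d, converted from GHz to eV. This is the (tiny) energy
#' transfer attached to the elastic dipole channel's kinematics.
#'
#' @param B_d Rotational constant(s), GHz (>= 0); vectorized.
#' @return Energy in eV.
#' @examples
#' rotational_quantum(5.40)
#' @export
rotational_quantum <- function(B_d) {
  if (any(!is.finite(B_d)) || any(B_d < 0))
    stop("B_d must be finite and >= 0 (GHz)", call. = FALSE)
  2 * physical_constants()$ghz_ev * B_d
}

#' Deterministic synthetic species for tests
#'
#' Generates a random but reproducible species whose parameter ranges
#' bracket the MAA conformer values; always passes [validate_species()].
#' The caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_orbitals Number of orbitals (>= 1); the HOMO binding energy
#'   equals the ionization threshold.
#' @param n_excitations Number of excited states (>= 0).
#' @return A validated [molecular_species()].
#' @export
make_toy_species <- function(seed, n_orbitals = 4, n_excitations = 2) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_orbitals >= 1, n_excitations >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)

  comps <- round(runif(3, -4.5, 4.5), 3)
  if (all(abs(comps) < 0.2)) comps[1] <- 1.5  # keep the channel open
  e_ion <- round(runif(1, 9, 11.5), 3)
  extra <- if (n_orbitals > 1)
    sort(round(runif(n_orbitals - 1, e_ion + 0.5, 40), 3)) else numeric(0)
  b <- c(e_ion, extra)
  orbital_table <- data.frame(
    binding_ev = b,
    kinetic_ev = round(b * runif(n_orbitals, 1.2, 3.0), 3),
    occupation = 2,
    q = round(runif(n_orbitals, 0.5, 1.5), 3))
  gap <- round(runif(1, 4.5, 6.5), 3)
  exc_e <- if (n_excitations > 0)
    gap + c(0, cumsum(round(runif(max(0, n_excitations - 1), 0.5, 2), 3)))
  else numeric(0)
  excitation_table <- if (n_excitations > 0) data.frame(
    energy_ev = exc_e,
    transition_dipole_debye = round(runif(n_excitations, 0.5, 4), 3)) else NULL

  molecular_species(
    name = sprintf("toy-%d", as.integer(seed)),
    dipole_components = comps,
    rotational_constants = round(runif(3, 2, 6), 3),
    orbital_table = orbital_table,
    excitation_table = excitation_table,
    ionization_threshold = e_ion,
    electron_affinity = round(runif(1, 0.3, 0.7), 3),
    gap_energy = gap)
}

#' Toy medium for tests
#'
#' @param trap_strength,trap_exponent Polaron parameters (defaults give a
#'   weak but active trapping channel).
#' @param eps_static,eps_highfreq,phonon_energy,temperature,number_density
#'   Remaining bulk parameters.
#' @return A validated [medium_properties()].
#' @export
make_toy_medium <- function(number_density = 7.1e27, phonon_energy = 0.1,
                            eps_static = 3.9, eps_highfreq = 2.2,
                            temperature = 298.15, trap_strength = 5e8,
                            trap_exponent = 0.25) {
  medium_properties(number_density, phonon_energy, eps_static, eps_highfreq,
                    temperature, trap_strength, trap_exponent)
}

# internal: species+medium flattened to the engine's parameter list
# (dipoles squared in atomic units, thresholds in eV)
engine_pars <- function(species, medium) {
  pc <- physical_constants()
  d_au2 <- (species$dipole_components * pc$debye_au)^2
  dw <- rotational_quantum(species$rotational_constants)
  et <- species$excitation_table
  ot <- species$orbital_table
  list(
    el_d2 = as.numeric(d_au2),
    el_dw = as.numeric(dw),
    ex_d2 = as.numeric((et$transition_dipole_debye * pc$debye_au)^2),
    ex_de = as.numeric(et$energy_ev),
    orb_b = as.numeric(ot$binding_ev),
    orb_u = as.numeric(ot$kinetic_ev),
    orb_n = as.numeric(ot$occupation),
    orb_q = as.numeric(ot$q),
    e_ion = species$ionization_threshold,
    ndens = medium$number_density,
    hw_ph = medium$phonon_energy,
    eps0 = medium$eps_static,
    epsinf = medium$eps_highfreq,
    temp = medium$temperature,
    strap = medium$trap_strength,
    gtrap = medium$trap_exponent)
}
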