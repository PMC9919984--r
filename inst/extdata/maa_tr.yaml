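# Methacrylic acid conformer TR in a gel medium.
#
# species: dipole_components_debye, rotational_constants_ghz,
# ionization_threshold_ev, electron_affinity_ev and gap_energy_ev are the
# published quantum-chemistry values for this conformer (signs of the
# threshold/affinity follow the positive-magnitude convention).
#
# ASSUMED, NOT FROM THE SOURCE PUBLICATION: the 'orbitals' ladder below
# the HOMO (synthetic valence B_i/U_i values typical of a small
# carboxylic acid; the 6 core orbitals are omitted), the 'excitations'
# table beyond placing the first intense state at the gap energy, and
# the entire 'medium' block (literature-typical values for a polar
# organic insulator). See the methods vignette.
species:
  name: TR
  dipole_components_debye: [-2.97, 2.95, 0.82]
  rotational_constants_ghz: [5.30, 3.41, 2.19]
  ionization_threshold_ev: 10.647
  electron_affinity_ev: 0.418
  gap_energy_ev: 6.08
  orbitals:
    - {binding_ev: 10.647, kinetic_ev: 23.42, occupation: 2, q: 1.0}
    - {binding_ev: 11.900, kinetic_ev: 24.99, occupation: 2, q: 1.0}
    - {binding_ev: 12.800, kinetic_ev: 25.60, occupation: 2, q: 1.0}
    - {binding_ev: 13.600, kinetic_ev: 27.20, occupation: 2, q: 1.0}
    - {binding_ev: 14.400, kinetic_ev: 27.36, occupation: 2, q: 1.0}
    - {binding_ev: 15.300, kinetic_ev: 29.07, occupation: 2, q: 1.0}
    - {binding_ev: 16.200, kinetic_ev: 29.16, occupation: 2, q: 1.0}
    - {binding_ev: 17.300, kinetic_ev: 31.14, occupation: 2, q: 1.0}
    - {binding_ev: 18.300, kinetic_ev: 32.94, occupation: 2, q: 1.0}
    - {binding_ev: 19.600, kinetic_ev: 33.32, occupation: 2, q: 1.0}
    - {binding_ev: 21.600, kinetic_ev: 36.72, occupation: 2, q: 1.0}
    - {binding_ev: 23.400, kinetic_ev: 37.44, occupation: 2, q: 1.0}
    - {binding_ev: 25.300, kinetic_ev: 40.48, occupation: 2, q: 1.0}
    - {binding_ev: 28.600, kinetic_ev: 42.90, occupation: 2, q: 1.0}
    - {binding_ev: 32.400, kinetic_ev: 48.60, occupation: 2, q: 1.0}
    - {binding_ev: 36.700, kinetic_ev: 51.38, occupation: 2, q: 1.0}
    - {binding_ev: 39.400, kinetic_ev: 55.16, occupation: 2, q: 1.0}
  excitations:
    - {energy_ev: 6.08, transition_dipole_debye: 3.70}
    - {energy_ev: 7.60, transition_dipole_debye: 1.80}
    - {energy_ev: 9.20, transition_dipole_debye: 1.30}
medium:
  number_density_m3: 7.1e27      # from liquid-MAA density 1.015 g/cm3, M = 86.09 g/mol
  phonon_energy_ev: 0.10         # LO phonon, typical polar organic solid
  eps_static: 3.9
  eps_highfreq: 2.2
  temperature_k: 298.15
  trap_strength_m1: 5.0e8        # Ganachaud-Mokrani-typical insulator trap
  trap_exponent_ev1: 0.25
beam:
  energy_ev: 1000
  n_trajectories: 10000
  seed: 42
output:
  directory: "."
  bin_width_ev: 0.5
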