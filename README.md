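# seymc

Monte Carlo simulation of secondary electron emission from gels of polar
organic molecules, with the four conformers of methacrylic acid (MAA) —
cis-chain `CC`, cis-ring `CR`, trans-chain `TC`, trans-ring `TR` — bundled
as reference materials.

## What it computes

An electron beam (sub-eV to 10 keV) hits the flat surface of a
semi-infinite homogeneous gel. Every primary electron and every secondary
it liberates is followed collision by collision (track-structure Monte
Carlo with energy straggling) until it escapes through the surface, is
trapped as a polaron, or drops below the tracking cutoff. The code
reports:

* **SEY** (secondary electron yield): emitted electrons with energy below
  50 eV per incident primary;
* **BC** (backscattering coefficient): emitted electrons at or above
  50 eV per primary;
* the emission energy spectrum, per-channel cross-section tables and the
  inelastic mean free path.

Five analytic collision channels compete at each step:

1. **elastic scattering** from the rotating permanent dipole (first Born
   approximation, one term per inertia axis),
2. **electronic excitation** driven by transition dipole moments (same
   Born closed form),
3. **impact ionization** per molecular orbital (Binary-Encounter-Bethe),
4. **optical-phonon creation** (Fröhlich coupling), and
5. **polaron trapping** (exponential capture).

All outcome variables (deflection angles, ejected-electron energies) are
drawn by inverse-transform sampling from closed-form cumulative
distributions; the per-event loop runs in compiled code (Rcpp) and every
transport rule is also exposed as a testable R function. See the methods
vignette (`vignettes/electron-cascades-maa.Rmd`) for the formulas,
numerical-conditioning choices and known limitations.

## Worked example

```r
library(seymc)

cc  <- maa_conformer("CC")   # bundled fixture
med <- maa_medium()

cc
#> <molecular_species> CC
#>   |D| = 1.907 Debye  (components 1.44, -1.25, 0.00)
#>   B_d = 5.33, 3.52, 2.15 GHz
#>   17 orbitals (HOMO 10.256 eV), 3 excited states, E_ion 10.256 eV, E_EA 0.580 eV, E_gap 5.83 eV

build_cross_section_set(100, cc, med)
#> <cross_section_set> E = 100 eV
#>   el 2.908e-20  elec 3.776e-20  ion 1.200e-19  phonon 2.233e-21  polaron 9.780e-31 m^2
#>   total 1.891e-19 m^2, lambda 7.450e-10 m, p = (0.1538, 0.9882, 1.0000, 1)

res <- run_simulation(beam_config(350, n_trajectories = 1e4, seed = 42),
                      cc, med)
res
#> <simulation_result> E_beam = 350 eV, 10000 primaries (seed 42)
#>   SEY = 0.6974, BC = 0.0256 (cutoff 0.580 eV)
#>   emitted 7230, trapped 188464, absorbed 68356, secondaries 254050, events 6.25198e+06

head(res$spectrum, 4)
#>   E_low E_high counts  dY_dE
#> 1   0.0    0.5      0 0.0000
#> 2   0.5    1.0    346 0.0692
#> 3   1.0    1.5    473 0.0946
#> 4   1.5    2.0    546 0.1092

sweep_beam_energy(c(50, 150, 350, 1000), cc, med,
                  n_trajectories = 5e3, seed = 42)
#>   E_beam_eV    sey     bc     sey_se        bc_se emitted trapped
#> 1        50 0.6526 0.0016 0.01142454 0.0005656854    3271   13221
#> 2       150 0.9132 0.0094 0.01351444 0.0013711309    4613   38974
#> 3       350 0.6938 0.0298 0.01177964 0.0024413111    3618   93774
#> 4      1000 0.3362 0.0394 0.00820000 0.0028071338    1878  271421
```

The SEY rises to a maximum near 150 eV and falls off at higher beam
energy, while BC grows monotonically — the classic emission-yield shape.
Runs are exactly reproducible for a given seed (each trajectory has its
own counter-based random stream).

The same functionality is available from the command line:

```sh
inst/cli/seymc xsec     --conformer CC --energies 10,100,1000
inst/cli/seymc simulate --conformer TR --beam-energy 350 --seed 42 --out runs/
inst/cli/seymc sweep    --conformer CC --energies 50,150,350,1000 --seed 42
inst/cli/seymc validate --conformer CC      # built-in invariant checks
```

## Configuration files

Materials are YAML documents with `species`, `medium` and optional
`beam`/`output` blocks; see `inst/extdata/maa_cc.yaml` for the full key
reference. Per conformer, the dipole components, rotational constants,
ionization threshold, electron affinity and gap energy are published
quantum-chemistry values; the orbital ladder below the HOMO, the higher
excitation entries and the entire medium block (density, phonon energy,
dielectric constants, trap parameters) are **documented placeholders**
(marked `ASSUMED` in the files) — they set a reasonable polar-organic
insulator, not a fitted material. Absolute SEY/BC values characterize
this parameterization; see the vignette's "Known limitations".

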