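Package: seymc
Title: Monte Carlo Simulation of Secondary Electron Emission from Polar
    Molecular Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Track-structure Monte Carlo simulation of low-energy electron
    transport in gels of polar organic molecules, with methacrylic acid
    conformers as the bundled reference material. Five analytic collision
    channels are implemented: elastic scattering from the rotating molecular
    dipole in the first Born approximation, electronic excitation from
    transition dipoles, electron-impact ionization in the Binary-Encounter
    Bethe model, longitudinal optical phonon creation in the Froehlich
    picture, and polaron trapping. Scattering angles and ejected-electron
    energies are drawn by inverse-transform sampling from closed-form
    cumulative probabilities. Secondary-electron cascades are followed in a
    semi-infinite slab, and emission spectra, the secondary electron yield
    and the backscattering coefficient are computed as functions of beam
    energy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
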