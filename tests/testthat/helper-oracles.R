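# Independent R transcriptions of the analytic cross sections, used as
# oracles against the compiled implementations. Kept deliberately separate
# from the package internals: plain formulas, no shared helpers.

or_const <- list(
  a0       = 0.529e-10,          # Bohr radius, m
  hartree  = 27.211386245988,    # eV
  rydberg  = 13.6,               # eV, as used by the BEB prefactor
  debye_au = 0.3934302014076827, # 1 Debye in atomic units
  ghz_ev   = 4.135667696e-6      # h * 1 GHz in eV
)

or_k <- function(E) sqrt(2 * E / or_const$hartree)  # wavenumber, a.u.

# Per-axis charge--rotating-dipole cross section (first Born), m^2.
# D_debye: dipole component in Debye; dw_ev: rotational energy transfer.
or_dipole_sigma <- function(E, D_debye, dw_ev) {
  if (E <= dw_ev) return(0)
  k <- or_k(E); kd <- or_k(E - dw_ev)
  D2 <- (D_debye * or_const$debye_au)^2
  (8 * pi / (3 * k^2)) * D2 * log((k + kd) / (k - kd)) * or_const$a0^2
}

# Per-axis differential cross section in t = 1 - cos(theta), m^2/sr:
# dcs = 4 D^2 kd / (3 k ((k - kd)^2 + 2 k kd t))
or_dipole_dcs_t <- function(t, E, D_debye, dw_ev) {
  k <- or_k(E); kd <- or_k(E - dw_ev)
  dk <- (2 * dw_ev / or_const$hartree) / (k + kd)  # k - kd, cancellation-free
  D2 <- (D_debye * or_const$debye_au)^2
  4 * D2 * kd / (3 * k * (dk^2 + 2 * k * kd * t)) * or_const$a0^2
}

# Summed-axis elastic cross section for a species, m^2.
or_sigma_elastic <- function(E, species) {
  dw <- 2 * or_const$ghz_ev * species$rotational_constants
  sum(mapply(or_dipole_sigma, dw_ev = dw,
             MoreArgs = list(E = E), D_debye = species$dipole_components))
}

# BEB ionization cross section for one orbital row, m^2
# (Q = 1 dipole-less form when q = 1).
or_beb_sigma <- function(E, B, U, N, Q = 1) {
  t <- E / B
  if (t <= 1) return(0)
  u <- U / B
  S <- 4 * pi * or_const$a0^2 * N * (or_const$rydberg / B)^2
  S / (t + u + 1) * ((2 - Q) * (1 - 1 / t - log(t) / (t + 1)) +
                     0.5 * Q * log(t) * (1 - 1 / (t * t)))
}

# BEB singly-differential cross section in the ejected energy W, m^2/eV.
# w = W/B, t = E/B; symmetric-in-(w, t-1-w) Mott + dipole terms.
or_beb_diff <- function(W, E, B, U, N, Q = 1) {
  t <- E / B; u <- U / B; w <- W / B
  S <- 4 * pi * or_const$a0^2 * N * (or_const$rydberg / B)^2
  f2 <- (2 - Q) * (1 / (w + 1)^2 + 1 / (t - w)^2)
  f3 <- Q * log(t) * (1 / (w + 1)^3 + 1 / (t - w)^3)
  S / (B * (t + u + 1)) * (f2 + f3 - (2 - Q) / ((w + 1) * (t - w)))
}

# Froehlich phonon-creation cross section, m^2.
or_phonon_sigma <- function(E, medium) {
  hw <- medium$phonon_energy
  if (E <= hw) return(0)
  kB <- 8.617333262e-5  # eV/K
  n <- 1 / (exp(hw / (kB * medium$temperature)) - 1)
  pref <- (1 / medium$number_density) * (1 / or_const$a0) * (n + 1) / 2 *
    (medium$eps_static - medium$eps_highfreq) /
    (medium$eps_static * medium$eps_highfreq)
  s <- sqrt(1 - hw / E)
  pref * (hw / E) * log((1 + s) / (1 - s))
}

# Polaron-trapping cross section, m^2.
or_polaron_sigma <- function(E, medium) {
  medium$trap_strength / medium$number_density *
    exp(-medium$trap_exponent * E)
}

# Quadrature of the BEB differential over the ejected energy, in
# v = log(W + B): the integrand decays like W^-2, so a linear-in-W
# adaptive quadrature under-resolves the peak at W = 0 for large E
# (stats::integrate can return with a silently huge error estimate there).
or_beb_quad <- function(E, B, U, N, Q = 1) {
  wmax <- (E - B) / 2
  f <- function(v) {
    W <- pmax(exp(v) - B, 0)
    or_beb_diff(pmin(W, wmax), E, B, U, N, Q) * (W + B)
  }
  stats::integrate(f, log(B), log(wmax + B), rel.tol = 1e-12,
                   subdivisions = 1000L)$value
}

# Quadrature of the package's own dcs_elastic over solid angle,
# 2 pi Int dcs(theta) sin(theta) dtheta. The integrand is extremely
# forward peaked at keV energies, so the small-angle part is integrated
# in v = log(theta); the probability mass below theta = 1e-12 is
# O(1e-10) of the total and is neglected.
or_quadrature_dcs <- function(E, species, split = 0.1) {
  f <- function(theta) {
    2 * pi * dcs_elastic(theta, E, species) * sin(theta)
  }
  low <- stats::integrate(function(v) f(exp(v)) * exp(v),
                          log(1e-12), log(split),
                          rel.tol = 1e-9, subdivisions = 1000L)
  high <- stats::integrate(f, split, pi,
                           rel.tol = 1e-9, subdivisions = 1000L)
  low$value + high$value
}
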