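# Channel formulas vs the independent R oracles in helper-oracles.R, plus
# structural invariants of the sampling layer.

species_pool <- function() {
  c(lapply(c("CC", "CR", "TC", "TR"), maa_conformer),
    list(make_toy_species(31), make_toy_species(32)))
}

test_that("elastic cross section matches the per-axis oracle", {
  for (sp in species_pool()) {
    for (E in c(0.5, 5, 50, 500, 5000)) {
      expect_equal(sigma_elastic(E, sp), or_sigma_elastic(E, sp),
                   tolerance = 1e-12, info = sprintf("%s @ %g eV", sp$name, E))
    }
  }
})

test_that("elastic cross section is vectorized and decreasing in E", {
  sp <- maa_conformer("CC")
  E <- c(10, 100, 1000)
  expect_equal(sigma_elastic(E, sp),
               vapply(E, sigma_elastic, 0, species = sp))
  s <- sigma_elastic(10^seq(0, 4, by = 0.25), sp)
  expect_true(all(diff(s) < 0))
  expect_error(sigma_elastic(-1, sp))
  expect_error(sigma_elastic(0, sp))
})

test_that("elastic dcs matches the oracle away from and inside the peak", {
  sp <- maa_conformer("TR")
  dw <- rotational_quantum(sp$rotational_constants)
  for (E in c(20, 1000)) {
    for (theta in c(1e-9, 1e-6, 1e-3, 0.1, 1, pi / 2, pi)) {
      t <- 2 * sin(theta / 2)^2
      want <- sum(mapply(or_dipole_dcs_t, dw_ev = dw,
                         D_debye = sp$dipole_components,
                         MoreArgs = list(t = t, E = E)))
      expect_equal(dcs_elastic(theta, E, sp), want, tolerance = 1e-10)
    }
  }
})

test_that("cumulative elastic angle has exact endpoints and is monotone", {
  for (sp in species_pool()) {
    for (E in c(1, 100, 5000)) {
      expect_identical(cumulative_elastic(0, E, sp), 0)
      expect_equal(cumulative_elastic(pi, E, sp), 1)
      th <- seq(1e-8, pi, length.out = 200)
      expect_true(all(diff(cumulative_elastic(th, E, sp)) > 0))
    }
  }
  expect_error(cumulative_elastic(-0.1, 100, maa_conformer("CC")))
  expect_error(cumulative_elastic(pi + 0.1, 100, maa_conformer("CC")))
})

test_that("elastic angle sampler inverts its own cumulative to 1e-10", {
  set.seed(41)
  for (sp in species_pool()) {
    for (E in c(2, 200, 8000)) {
      mu <- c(0, runif(25), 1)
      th <- sample_elastic_angle(mu, E, sp)
      expect_true(all(th >= 0 & th <= pi))
      expect_equal(cumulative_elastic(th, E, sp), mu, tolerance = 1e-10)
    }
  }
})

test_that("sampled elastic angles reproduce the cumulative distribution", {
  # two-sided check of the sampler against the analytic CDF at fixed
  # quantiles (Kolmogorov-style bound, n = 20000)
  sp <- maa_conformer("CC")
  set.seed(71)
  th <- sample_elastic_angle(runif(20000), 150, sp)
  p <- cumulative_elastic(quantile(th, c(0.1, 0.5, 0.9), names = FALSE),
                          150, sp)
  expect_lt(max(abs(p - c(0.1, 0.5, 0.9))), 0.015)
})

test_that("excitation channel opens at the first excitation energy", {
  sp <- maa_conformer("CC")
  e1 <- min(sp$excitation_table$energy_ev)
  expect_equal(sigma_excitation(e1 * 0.999, sp), 0)
  expect_gt(sigma_excitation(e1 * 1.001, sp), 0)
  st <- sigma_excitation_states(100, sp)
  expect_equal(sum(st$sigma_m2), sigma_excitation(100, sp))
  expect_equal(nrow(st), nrow(sp$excitation_table))
})

test_that("excited-state sampling follows the per-state weights", {
  # two equal-weight open states: mu = 0.5 falls on the closed side of the
  # first interval and must select the second state
  sp <- make_toy_species(5, n_excitations = 0)
  sp$excitation_table <- data.frame(energy_ev = c(5, 5),
                                    transition_dipole_debye = c(2, 2))
  sp <- validate_species(sp)
  expect_identical(sample_excited_state(0.49, 50, sp), 1L)
  expect_identical(sample_excited_state(0.5, 50, sp), 2L)
  expect_identical(sample_excited_state(0, 50, sp), 1L)

  nochan <- make_toy_species(6, n_excitations = 0)
  expect_error(sample_excited_state(0.5, 50, nochan), "no open excitation")
})

test_that("BEB orbital cross section matches the oracle and its threshold", {
  for (sp in species_pool()) {
    ot <- sp$orbital_table
    for (i in seq_len(nrow(ot))) {
      orb <- ot[i, ]
      expect_equal(sigma_beb_orbital(orb$binding_ev, orb), 0)  # t = 1
      expect_equal(sigma_beb_orbital(orb$binding_ev * 0.9, orb), 0)
      for (E in c(15, 80, 1200)) {
        if (E <= orb$binding_ev) next
        expect_equal(sigma_beb_orbital(E, orb),
                     or_beb_sigma(E, orb$binding_ev, orb$kinetic_ev,
                                  orb$occupation, orb$q),
                     tolerance = 1e-12)
      }
    }
    expect_equal(sigma_ionization(300, sp),
                 sum(vapply(seq_len(nrow(ot)), function(i)
                   sigma_beb_orbital(300, ot[i, ]), 0)))
  }
})

test_that("BEB cumulative has exact endpoints and quadrature matches", {
  sp <- maa_conformer("CC")
  homo <- sp$orbital_table[which.min(sp$orbital_table$binding_ev), ]
  B <- homo$binding_ev
  for (E in c(25, 120, 900)) {
    wmax <- (E - B) / 2
    expect_equal(cumulative_beb(0, E, homo), 0)
    expect_equal(cumulative_beb(wmax, E, homo), 1, tolerance = 1e-12)
    w <- seq(0, wmax, length.out = 100)
    expect_true(all(diff(cumulative_beb(w, E, homo)) > 0))
    # numerical quadrature of the differential oracle vs the closed form
    q <- or_beb_quad(E, B, homo$kinetic_ev, homo$occupation, homo$q)
    expect_equal(q, sigma_beb_orbital(E, homo), tolerance = 1e-8)
  }
  expect_error(cumulative_beb(1, B * 0.5, homo), "binding")
  expect_error(cumulative_beb(-1, 100, homo))
  expect_error(cumulative_beb(1e6, 100, homo))
})

test_that("ejected-energy sampler inverts the BEB cumulative", {
  set.seed(13)
  for (sp in species_pool()) {
    homo <- sp$orbital_table[which.min(sp$orbital_table$binding_ev), ]
    for (E in c(30, 400)) {
      mu <- c(0, runif(20), 1)
      w <- sample_ejected_energy(mu, E, sp)
      expect_true(all(w >= 0 & w <= (E - homo$binding_ev) / 2))
      expect_equal(cumulative_beb(w, E, homo), mu, tolerance = 1e-7)
    }
    expect_error(sample_ejected_energy(0.5, homo$binding_ev * 0.9, sp),
                 "HOMO")
  }
})

test_that("phonon cross section matches the oracle and closes below hw", {
  md <- maa_medium()
  hw <- md$phonon_energy
  expect_equal(sigma_phonon(hw, md), 0)
  expect_equal(sigma_phonon(hw / 2, md), 0)
  for (E in c(hw * 1.01, 1, 10, 1000)) {
    expect_equal(sigma_phonon(E, md), or_phonon_sigma(E, md),
                 tolerance = 1e-12)
  }
})

test_that("phonon deflection angle has exact endpoints and is monotone", {
  for (pair in list(c(10, 9.9), c(0.2, 0.1), c(1000, 999.9))) {
    E <- pair[1]; Ep <- pair[2]
    expect_equal(sample_phonon_angle(0, E, Ep), 0)
    expect_equal(sample_phonon_angle(1, E, Ep), pi, tolerance = 1e-3)
    mu <- seq(0, 1, length.out = 101)
    th <- sample_phonon_angle(mu, E, Ep)
    expect_true(all(diff(th) > 0))
  }
  expect_error(sample_phonon_angle(0.5, 1, 2), "Eprime")
  expect_error(sample_phonon_angle(0.5, 1, 1), "Eprime")
})

test_that("polaron cross section matches the oracle and allows E = 0", {
  md <- maa_medium()
  for (E in c(0, 0.5, 5, 100)) {
    expect_equal(sigma_polaron(E, md), or_polaron_sigma(E, md),
                 tolerance = 1e-14)
  }
  s <- sigma_polaron(seq(0, 20, by = 0.5), md)
  expect_true(all(diff(s) < 0))  # exponential decay
  nomedium_traps <- make_toy_medium(trap_strength = 0)
  expect_equal(sigma_polaron(3, nomedium_traps), 0)
})

test_that("cross_section_set assembles consistent probabilities", {
  sp <- maa_conformer("CR"); md <- maa_medium()
  for (E in c(0.05, 4, 75, 2000)) {
    css <- build_cross_section_set(E, sp, md)
    tot <- css$sigma_el + css$sigma_elec + css$sigma_ion +
      css$sigma_phonon + css$sigma_polaron
    expect_equal(css$sigma_total, tot)
    expect_equal(css$lambda_total, 1 / (md$number_density * tot))
    expect_true(css$p1 >= 0 && css$p1 <= css$p2 && css$p2 <= css$p3 &&
                css$p3 <= 1)
    expect_identical(css$p4, 1)
    expect_equal(css$p1, css$sigma_el / tot)
  }
})

test_that("inelastic mean free path is Inf below both electronic channels", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  e1 <- min(sp$excitation_table$energy_ev)
  expect_identical(inelastic_mean_free_path(e1 * 0.99, sp, md), Inf)
  E <- 100
  expect_equal(inelastic_mean_free_path(E, sp, md),
               1 / (md$number_density *
                    (sigma_excitation(E, sp) + sigma_ionization(E, sp))))
})

test_that("cross_section_table matches the individual channels", {
  sp <- maa_conformer("TC"); md <- maa_medium()
  E <- c(1, 10, 100, 1000)
  tab <- cross_section_table(E, sp, md)
  expect_named(tab, c("E_eV", "sigma_el_m2", "sigma_elec_m2", "sigma_ion_m2",
                      "sigma_phonon_m2", "sigma_polaron_m2", "sigma_tot_m2",
                      "imfp_m"))
  expect_equal(tab$sigma_el_m2, sigma_elastic(E, sp))
  expect_equal(tab$sigma_ion_m2, sigma_ionization(E, sp))
  expect_equal(tab$sigma_tot_m2,
               tab$sigma_el_m2 + tab$sigma_elec_m2 + tab$sigma_ion_m2 +
               tab$sigma_phonon_m2 + tab$sigma_polaron_m2)
  expect_equal(tab$imfp_m, inelastic_mean_free_path(E, sp, md))
})
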