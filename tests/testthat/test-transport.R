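# Transport operators (R level) and the cascade engine's conservation laws.

test_that("step sampling is the exponential inverse transform", {
  expect_equal(sample_step(1, 2e-9), 0)
  expect_equal(sample_step(exp(-1), 3e-9), 3e-9)
  expect_error(sample_step(0, 1e-9), "redraw")
  expect_error(sample_step(1.5, 1e-9))
  expect_error(sample_step(0.5, 0), "lambda")
  set.seed(21)
  s <- sample_step(runif(2e5), 2e-9)
  # mean = lambda within 3 standard errors (sd = lambda for exponential)
  expect_lt(abs(mean(s) - 2e-9), 3 * 2e-9 / sqrt(2e5))
})

test_that("process selection uses half-open cumulative intervals", {
  css <- build_cross_section_set(100, maa_conformer("CC"), maa_medium())
  eps <- 1e-12
  expect_identical(select_process(0, css), "elastic")
  expect_identical(select_process(css$p1 - eps, css), "elastic")
  expect_identical(select_process(css$p1, css), "inelastic")
  expect_identical(select_process(css$p2 - eps, css), "inelastic")
  expect_identical(select_process(css$p2, css), "phonon")
  expect_identical(select_process(css$p3, css), "polaron")
  expect_identical(select_process(1 - eps, css), "polaron")
  expect_error(select_process(1, css))
  expect_error(select_process(-0.1, css))
  expect_length(select_process(c(0, 0.5, 0.999), css), 3)
})

test_that("process frequencies match the cumulative probabilities", {
  css <- build_cross_section_set(40, maa_conformer("TR"), maa_medium())
  set.seed(33)
  draws <- select_process(runif(2e5), css)
  obs <- table(factor(draws, c("elastic", "inelastic", "phonon", "polaron")))
  p <- c(css$p1, css$p2 - css$p1, css$p3 - css$p2, 1 - css$p3)
  keep <- p > 0
  chi <- suppressWarnings(
    stats::chisq.test(as.numeric(obs[keep]), p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.001)
})

test_that("rotate_direction preserves norm and realizes the polar angle", {
  set.seed(3)
  for (i in 1:20) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    theta <- runif(1, 0, pi); phi <- runif(1, 0, 2 * pi)
    out <- rotate_direction(d, theta, phi)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    expect_equal(sum(out * d), cos(theta), tolerance = 1e-10)
  }
  # stable at the poles
  expect_equal(sum(rotate_direction(c(0, 0, 1), 0.3, 1)^2), 1)
  expect_equal(rotate_direction(c(0, 0, -1), 0, 0), c(0, 0, -1))
  expect_error(rotate_direction(c(0, 0, 0), 1, 1))
  expect_error(rotate_direction(c(0, 0, 1), -0.1, 0))
})

test_that("inelastic operator conserves energy exactly", {
  sp <- maa_conformer("CC")
  homo_b <- min(sp$orbital_table$binding_ev)

  # excitation branch: below the ionization threshold
  st <- electron_state(energy = 8)
  out <- apply_inelastic(st, sp, mu = c(0.3, 0.5, 0.5))
  expect_null(out$secondary)
  loss <- 8 - out$primary$energy
  expect_true(any(abs(loss - sp$excitation_table$energy_ev) < 1e-12))

  # ionization branch: E = E' + W + B_HOMO, secondary one generation later
  st <- electron_state(energy = 200, generation = 2L)
  out <- apply_inelastic(st, sp, mu = c(0.7, 0.2, 0.9))
  expect_s3_class(out$secondary, "electron_state")
  expect_equal(out$primary$energy + out$secondary$energy + homo_b, 200)
  expect_identical(out$secondary$generation, 3L)
  expect_equal(sum(out$secondary$direction^2), 1, tolerance = 1e-12)
  expect_equal(out$secondary$position, st$position)
})

test_that("phonon operator subtracts one quantum and deflects", {
  md <- maa_medium()
  st <- electron_state(energy = 5)
  out <- apply_phonon(st, md, mu = c(0.4, 0.1))
  expect_equal(out$energy, 5 - md$phonon_energy)
  expect_equal(sum(out$direction^2), 1, tolerance = 1e-12)
  low <- electron_state(energy = md$phonon_energy / 2)
  expect_error(apply_phonon(low, md), "closed")
})

test_that("polaron operator marks the electron trapped", {
  st <- electron_state(energy = 1.2)
  out <- apply_polaron(st)
  expect_identical(attr(out, "status"), "trapped")
  expect_equal(out$energy, 1.2)
})

test_that("electron_state and beam_config validate their inputs", {
  expect_error(electron_state(energy = -1), "energy")
  expect_error(electron_state(direction = c(0, 0, 0), energy = 1))
  st <- electron_state(direction = c(0, 0, 2), energy = 1)
  expect_equal(st$direction, c(0, 0, 1))  # renormalized
  expect_error(beam_config(0), "beam energy")
  expect_error(beam_config(-5), "beam energy")
  expect_error(beam_config(100, n_trajectories = 0))
  expect_error(beam_config(100, cutoff = -1))
  b <- beam_config(100, direction = c(0, 0, 3))
  expect_equal(b$direction, c(0, 0, 1))
})

test_that("simulations are reproducible for a seed and vary across seeds", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  b <- beam_config(300, n_trajectories = 400, seed = 17)
  r1 <- run_simulation(b, sp, md)
  r2 <- run_simulation(b, sp, md)
  expect_identical(r1$emitted, r2$emitted)
  expect_identical(r1$counters, r2$counters)
  expect_equal(r1$sey, r2$sey)
  b3 <- beam_config(300, n_trajectories = 400, seed = 18)
  r3 <- run_simulation(b3, sp, md)
  expect_false(identical(r1$emitted, r3$emitted))
})

test_that("electron count is conserved in every run", {
  sp <- maa_conformer("TR"); md <- maa_medium()
  for (E in c(60, 500)) {
    r <- run_simulation(beam_config(E, n_trajectories = 500, seed = 4),
                        sp, md)
    ct <- r$counters
    expect_equal(ct$emitted + ct$trapped + ct$absorbed + ct$cap_terminated,
                 ct$primaries + ct$secondaries_created)
    expect_equal(nrow(r$emitted), ct$emitted)
    expect_equal(r$sey + r$bc, ct$emitted / ct$primaries)
  }
})

test_that("per-cascade energy balance closes to 1e-9 eV", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  r <- run_simulation(beam_config(800, n_trajectories = 300, seed = 9),
                      sp, md, residuals = TRUE)
  expect_length(r$residuals, 300)
  expect_lt(max(abs(r$residuals)), 1e-9)
})

test_that("a beam below the tracking cutoff is absorbed immediately", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  b <- beam_config(0.1, n_trajectories = 50, seed = 2, cutoff = 1)
  r <- run_simulation(b, sp, md)
  expect_equal(r$counters$absorbed, 50)
  expect_equal(r$counters$emitted, 0)
  expect_equal(r$sey, 0)
})

test_that("with only the elastic channel open, escapers keep full energy", {
  # Beam below every inelastic threshold, phonon quantum above the beam
  # energy, traps disabled: the walk is lossless, so every emitted electron
  # must carry exactly the beam energy, and the rest hit the event cap.
  sp <- make_toy_species(12, n_excitations = 0)
  md <- make_toy_medium(phonon_energy = 5, trap_strength = 0)
  b <- beam_config(3, n_trajectories = 300, seed = 8, max_events = 3e5)
  r <- run_simulation(b, sp, md)
  ct <- r$counters
  expect_equal(ct$secondaries_created, 0)
  expect_equal(ct$trapped, 0)
  expect_equal(ct$absorbed, 0)
  expect_equal(ct$emitted + ct$cap_terminated, ct$primaries)
  expect_true(all(r$emitted$energy == 3))
  # a diffusive walk from the surface escapes with high probability
  expect_gt(ct$emitted / ct$primaries, 0.9)
})

test_that("run_trajectory exposes trace, counters and residual", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  out <- run_trajectory(beam_config(150, seed = 6), sp, md)
  tr <- attr(out, "trace")
  expect_s3_class(tr, "data.frame")
  expect_true(all(c("trajectory", "generation", "process", "E_before",
                    "E_after", "z") %in% names(tr)))
  expect_true(nrow(tr) > 0)
  expect_true(all(tr$z >= 0))
  expect_true(all(tr$E_after <= tr$E_before + 1e-12))
  expect_lt(abs(attr(out, "residual")), 1e-9)
  expect_equal(attr(out, "counters")$primaries, 1)
})

test_that("sweep_beam_energy returns one row per energy with errors", {
  sp <- maa_conformer("CC"); md <- maa_medium()
  sw <- sweep_beam_energy(c(80, 300), sp, md, n_trajectories = 200, seed = 3)
  expect_equal(nrow(sw), 2)
  expect_named(sw, c("E_beam_eV", "sey", "bc", "sey_se", "bc_se",
                     "emitted", "trapped"))
  expect_true(all(sw$sey >= 0 & sw$bc >= 0))
  expect_true(all(sw$sey_se >= 0))
})

test_that("transport grid interpolation tracks the exact cross sections", {
  sp <- maa_conformer("CR"); md <- maa_medium()
  pars <- seymc:::engine_pars(sp, md)
  set.seed(14)
  E <- sort(exp(runif(40, log(0.6), log(999))))
  g <- seymc:::engine_interp_cpp(pars, 1000, 0.389, 2000L, E)
  for (i in seq_along(E)) {
    css <- build_cross_section_set(E[i], sp, md)
    expect_equal(g$lambda_m[i], css$lambda_total, tolerance = 5e-3)
    expect_equal(g$p1[i], css$p1, tolerance = 5e-3)
    expect_equal(g$p2[i], css$p2, tolerance = 5e-3)
    expect_equal(g$p3[i], css$p3, tolerance = 5e-3)
  }
})
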