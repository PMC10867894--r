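test_that("Ewald summation agrees with direct-image and Madelung oracles", {
  set.seed(31)
  # two opposite charges far apart in a large box: bare Coulomb limit
  tab <- default_species_table()
  L <- 40; lB <- 1; r <- 1.5
  st <- system_state(L, rbind(c(5, 5, 5), c(5, 5, 5 + r)),
                     c(match("Na+", tab$name), match("Cl-", tab$name)),
                     tab, lB = lB)
  expect_equal(total_energy(st)$electrostatic, -lB / r, tolerance = 1e-3)

  # direct summation over explicit periodic images (radius 8L), tinfoil
  st2 <- random_ion_state(3, L = 7, lB = 2)
  q <- st2$species_table$z[st2$species_idx]
  e_direct <- direct_coulomb_sum(st2$positions, q, st2$L, st2$lB)
  expect_equal(total_energy(st2)$electrostatic, e_direct, tolerance = 1e-3)

  # rocksalt Madelung constant, energy per ion pair = -1.747565 lB / a
  a <- 2
  stm <- rocksalt_state(a = a, lB = 1.3)
  expect_equal(total_energy(stm)$electrostatic / 4, -1.747565 * 1.3 / a,
               tolerance = 1e-3)

  # lattice-translation invariance
  stm2 <- stm
  stm2$positions <- stm$positions + stm$L
  expect_equal(total_energy(stm2)$electrostatic,
               total_energy(stm)$electrostatic, tolerance = 1e-10)

  # no charges -> exactly zero electrostatics
  chain <- build_single_chain(8)
  expect_identical(total_energy(chain)$electrostatic, 0)

  # non-neutral systems are refused
  bad <- st2
  bad$species_idx <- bad$species_idx[c(1, 1, 2:6)]
  expect_error(total_energy(bad), "neutral")
})

test_that("Langevin sampling is canonical: equipartition and oscillator variance", {
  set.seed(32)
  # free particles: kinetic energy per dof is kBT/2
  tab <- ideal_species()
  n <- 40
  st <- system_state(8, matrix(stats::runif(3 * n, 0, 8), n, 3),
                     rep(1L, n), tab)
  r <- run_langevin(st, langevin_params(gamma = 1, steps = 6000),
                    sample_every = 50)
  ke <- r$trajectory$energies[, "kinetic"] / (3 * n / 2)
  se <- stats::sd(ke) / sqrt(length(ke))
  expect_lt(abs(mean(ke) - 1), 3 * se + 0.02)

  # single harmonic bond: positional variance along the bond is kBT/K
  st2 <- build_single_chain(2)
  st2$exclude_bonded_wca <- TRUE
  r2 <- run_langevin(st2, langevin_params(steps = 150000), sample_every = 50)
  b <- vapply(r2$trajectory$frames,
              function(p) sqrt(sum((p[1, ] - p[2, ])^2)), numeric(1))
  # block the variance estimate for its standard error
  blocks <- split(b, cut(seq_along(b), 6, labels = FALSE))
  v <- vapply(blocks, stats::var, numeric(1))
  se_v <- stats::sd(v) / sqrt(length(v))
  # radial sampling of r^2 exp(-U): variance of r matches the quadrature
  mo <- dimer_bond_moments(st2$bond$k_bond, st2$bond$r0)
  expect_lt(abs(mean(v) - mo$var), 3 * se_v + 0.05 * mo$var)

  # particle count and species conserved by dynamics
  expect_identical(dim(r2$trajectory$frames[[1]]), c(2L, 3L))
})

test_that("deterministic limit is a second-order integrator", {
  set.seed(33)
  # harmonic dimer: the cleanest probe of the velocity-Verlet energy error
  st <- build_single_chain(2)
  st$exclude_bonded_wca <- TRUE
  st$velocities <- maxwell_velocities(2)
  drift <- vapply(c(0.01, 0.005), function(dt) {
    r <- run_langevin(st, langevin_params(gamma = 0, dt = dt, steps = 4000),
                      sample_every = 20, noise = FALSE)
    etot <- rowSums(r$trajectory$energies)
    sqrt(mean((etot - etot[1])^2))
  }, numeric(1))
  # halving dt reduces the energy error by ~4 (O(dt^2)); allow 2.5-7
  expect_gt(drift[1] / drift[2], 2.5)
  expect_lt(drift[1] / drift[2], 7)
})

test_that("virial pressure matches ideal-gas, volume-perturbation and B2 oracles", {
  set.seed(34)
  # non-interacting particles: P = N kBT / V identically in this estimator
  tab <- ideal_species()
  st <- system_state(10, matrix(stats::runif(90, 0, 10), 30, 3),
                     rep(1L, 30), tab)
  expect_equal(virial_pressure(st), 30 / 1000, tolerance = 1e-12)

  # frozen WCA + bonded configuration vs central-difference -dU/dV + NkT/V
  pec <- build_initial_pec(1, 6, 0.10, relax_steps = 100L, lB = 0)
  expect_equal(virial_pressure(pec), volume_perturbation_pressure(pec),
               tolerance = 1e-3)

  # frozen charged configuration (tight Ewald so both routes converge)
  stq <- random_ion_state(4, L = 8, lB = 2, accuracy = 1e-6)
  expect_equal(virial_pressure(stq), volume_perturbation_pressure(stq),
               tolerance = 1e-3)

  # dilute WCA fluid: P/(rho kBT) = 1 + B2 rho within 2%
  n <- 40; rho <- 0.02; L <- (n / rho)^(1 / 3)
  tabw <- species("W", 0, 1.2, 0)
  stw <- system_state(L, lattice_positions(n, L), rep(1L, n), tabw)
  r <- run_langevin(stw, langevin_params(steps = 20000), sample_every = 100,
                    sample_pressure = TRUE)
  z_meas <- mean(r$trajectory$pressures) / rho
  z_b2 <- 1 + b2_from_lambda(0, 1.2) * rho
  expect_equal(z_meas, z_b2, tolerance = 0.02)
})

test_that("PEC initialization reaches the target volume fraction", {
  set.seed(35)
  st <- build_initial_pec(2, 6, 0.12, relax_steps = 150L, lB = 0)
  expect_equal(volume_fraction(st, "monomers"), 0.12, tolerance = 1e-10)
  expect_true(all(st$positions >= 0 & st$positions < st$L))
  expect_identical(length(st$topology), 4L)
  expect_identical(state_net_charge(st), 0L)
  # a dilute target needs no compression: the box starts at its final edge
  dilute <- build_initial_pec(2, 6, 0.001, relax_steps = 20L, lB = 0)
  expect_equal(volume_fraction(dilute, "monomers"), 0.001, tolerance = 1e-10)
  # infeasible target beyond dense packing
  expect_error(build_initial_pec(2, 6, 0.7, relax_steps = 10L, lB = 0),
               "feasible")
  # the production geometry: phi in the typical 7-15% range implies boxes
  # of 23-30 sigma for 64 chains of 32 beads
  L_range <- box_edge_for_phi(2048, 1.2, c(0.15, 0.07))
  expect_gt(L_range[1], 22)
  expect_lt(L_range[2], 31)
})

test_that("mean bond length: stiff limit and dimer quadrature oracle", {
  set.seed(36)
  # stiff spring pins the bond at its rest length
  stiff <- bond_params(k_bond = 2e3, r0 = 1.2)
  st <- build_single_chain(4, bond = stiff)
  st$exclude_bonded_wca <- TRUE
  r <- run_langevin(st, langevin_params(steps = 20000), sample_every = 100)
  mb <- mean_bond_length(r$trajectory)
  expect_equal(mb$mean, 1.2, tolerance = 0.01)

  # harmonic-only isolated dimer matches the r^2-weighted Boltzmann mean
  st2 <- build_single_chain(2)
  st2$exclude_bonded_wca <- TRUE
  r2 <- run_langevin(st2, langevin_params(steps = 150000), sample_every = 50)
  mb2 <- mean_bond_length(r2$trajectory)
  mo <- dimer_bond_moments(st2$bond$k_bond, st2$bond$r0)
  expect_lt(abs(mb2$mean - mo$mean), 3 * mb2$stderr + 1e-4)
})
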