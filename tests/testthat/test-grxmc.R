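test_that("reaction specs enforce neutrality and monomer protection", {
  tab <- default_species_table()
  expect_s3_class(reaction_spec(c("Na+" = 1, "Cl-" = 1), 0.01), "reaction_spec")
  expect_error(reaction_spec(c("Na+" = 1), 0.01), "charge-neutral")
  expect_error(reaction_spec(c("A-" = -1, "Cl-" = -1), 0.01), "monomer")
  expect_error(reaction_spec(c("Na+" = 0), 0.01), "no species")
  expect_error(reaction_spec(c("Xx" = 1), 0.01), "unknown")
})

test_that("acceptance probability evaluates the reaction-ensemble formula", {
  tab <- default_species_table()
  counts0 <- stats::setNames(rep(0, nrow(tab)), tab$name)
  rx <- reaction_spec(c("Na+" = 1, "Cl-" = 1), K_gamma = 1)
  V <- 10 / molar_to_reduced(1) # so that V * c0 = 10 particle-number units
  # empty box, pair insertion: min(1, K (Vc)^2 / (1*1)) = min(1, 100) = 1
  expect_equal(acceptance_probability(counts0, rx, +1, 0, V), 1)
  # box holding exactly one pair, deletion: min(1, 1/100)
  counts1 <- counts0; counts1[c("Na+", "Cl-")] <- 1
  expect_equal(acceptance_probability(counts1, rx, -1, 0, V), 0.01,
               tolerance = 1e-12)
  # deletion from an empty box is impossible
  expect_identical(acceptance_probability(counts0, rx, -1, 0, V), 0)
  # infinitely unfavourable energy change
  expect_identical(acceptance_probability(counts0, rx, +1, Inf, V), 0)
})

test_that("acceptance ratios satisfy detailed balance on enumerated microstates", {
  # for Metropolis acceptance a = min(1, x), the ratio a_fwd/a_bwd between
  # two states must equal the exact ratio of their ensemble weights
  rx <- reaction_spec(c("Na+" = 1, "Cl-" = 1), K_gamma = 0.04)
  V <- 300
  Vc <- V * molar_to_reduced(1)
  tab <- default_species_table()
  for (N in 0:3) {
    counts_o <- stats::setNames(rep(0, nrow(tab)), tab$name)
    counts_o[c("Na+", "Cl-")] <- N
    counts_n <- counts_o + 1
    for (dE in c(0, -0.7, 1.3)) {
      a_f <- acceptance_probability(counts_o, rx, +1, dE, V)
      a_b <- acceptance_probability(counts_n, rx, -1, -dE, V)
      w_ratio <- rx$K_gamma * Vc^2 / (N + 1)^2 * exp(-dE)
      expect_equal(a_f / a_b, w_ratio, tolerance = 1e-12)
    }
  }
  # identity-changing reaction (first deprotonation) as well
  rx2 <- reaction_spec(c("H2SuA" = -1, "H+" = 1, "HSuA-" = 1), 10^(-4.2))
  counts_o <- stats::setNames(rep(0, nrow(tab)), tab$name)
  counts_o[c("H2SuA", "H+", "HSuA-")] <- c(2, 1, 0)
  counts_n <- counts_o
  counts_n[c("H2SuA", "H+", "HSuA-")] <- c(1, 2, 1)
  a_f <- acceptance_probability(counts_o, rx2, +1, 0, V)
  a_b <- acceptance_probability(counts_n, rx2, -1, 0, V)
  w_ratio <- rx2$K_gamma * Vc * 2 / (2 * 1)
  expect_equal(a_f / a_b, w_ratio, tolerance = 1e-12)
})

test_that("ideal-gas sampling reproduces grand-canonical mass action", {
  set.seed(41)
  tab <- default_species_table()
  cons <- constants_from_reservoir(pH = 7, c_salt = 0.15)
  st <- build_reservoir_box(14, cons$ideal_concentrations,
                            species_table = tab)
  out <- run_grxmc(st, cons$reactions, 6e4, interactions = "none",
                   sample_every = 10)
  V <- 14^3
  Vc <- V * molar_to_reduced(1)
  # exact grand-canonical identity: <N_Na N_Cl> = Gamma (V c0)^2
  prod_hat <- out$counts[, "Na+"] * out$counts[, "Cl-"] / Vc^2
  blocks <- split(prod_hat, cut(seq_along(prod_hat), 6, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(prod_hat) - 0.15^2), 4 * se)
  # product of mean concentrations approaches the same constant (finite-size
  # covariance correction is O(1/<N>))
  cNa <- reduced_to_molar(mean(out$counts[, "Na+"]) / V)
  cCl <- reduced_to_molar(mean(out$counts[, "Cl-"]) / V)
  expect_equal(cNa * cCl, 0.15^2, tolerance = 0.1)
})

test_that("ideal diprotic titration matches Henderson-Hasselbalch", {
  set.seed(42)
  tab <- default_species_table()
  for (pH in c(4.2, 4.9)) {
    cons <- constants_from_reservoir(pH = pH, c_salt = 0.05, c_acid = 0.01)
    st <- build_reservoir_box(14, cons$ideal_concentrations,
                              species_table = tab)
    out <- run_grxmc(st, cons$reactions, 8e4, interactions = "none",
                     sample_every = 20)
    acid <- c("H2SuA", "HSuA-", "SuA2-")
    tot <- rowSums(out$counts[, acid])
    keep <- tot > 0
    frac <- colMeans(out$counts[keep, acid] / tot[keep])
    ideal <- ideal_speciation(pH)
    # block errors on each fraction
    for (s in acid) {
      x <- out$counts[keep, s] / tot[keep]
      bm <- tapply(x, cut(seq_along(x), 6, labels = FALSE), mean)
      se <- stats::sd(bm) / sqrt(length(bm))
      expect_lt(abs(frac[[s]] - ideal[[s]]), 4 * se + 0.02)
    }
    # simulated fractions sum to 1 exactly (they are count ratios)
    expect_equal(unname(sum(frac)), 1, tolerance = 1e-12)
  }
})

test_that("electroneutrality and monomer protection hold during sampling", {
  set.seed(43)
  tab <- default_species_table()
  cons <- constants_from_reservoir(pH = 5, c_salt = 0.1, c_acid = 0.01,
                                   c_divalent = 0.02)
  st <- build_reservoir_box(10, cons$ideal_concentrations,
                            species_table = tab)
  z <- tab$z
  state <- st
  for (i in 1:40) {
    state <- run_grxmc(state, cons$reactions, 50, interactions = "none",
                       sample_every = 0)$state
    expect_identical(sum(z[state$species_idx]), 0L)
  }
  # direct deletion of a backbone particle is a hard error
  pec <- build_initial_pec(1, 4, 0.1, relax_steps = 20L, lB = 0)
  expect_error(pecsim:::state_remove_particles(pec, 1L), "backbone")
})

test_that("reservoir constants obey electroneutrality and cycle closure", {
  cons <- constants_from_reservoir(pH = 5.1, c_salt = 0.08, c_acid = 0.02)
  K <- stats::setNames(vapply(cons$reactions, function(r) r$K_gamma,
                              numeric(1)),
                       vapply(cons$reactions, function(r) r$label,
                              character(1)))
  # only two ion-pair constants are independent: electroneutrality fixes
  # the third through Gamma_NaCl * Gamma_w = Gamma_HCl * Gamma_NaOH
  expect_equal(K[["NaCl insertion"]] * K[["water autoionization"]],
               K[["HCl insertion"]] * K[["NaOH insertion"]],
               tolerance = 1e-12)
  # water ionic product
  expect_equal(K[["water autoionization"]], 1e-14, tolerance = 1e-12)
  # thermodynamic cycle closure of the composed solute-exchange constants
  expect_equal(K[["NaHSuA insertion"]],
               K[["H2SuA insertion"]] * 10^(-4.2) *
                 K[["NaOH insertion"]] / K[["water autoionization"]],
               tolerance = 1e-10)
  expect_equal(K[["Na2SuA insertion"]],
               K[["NaHSuA insertion"]] * 10^(-5.6) *
                 K[["NaOH insertion"]] / K[["water autoionization"]],
               tolerance = 1e-10)
  # pure water at pH 7: self-ion concentrations of 1e-7 each
  w <- constants_from_reservoir(pH = 7, c_salt = 0.01)
  expect_equal(w$ideal_concentrations[["H+"]], 1e-7)
  expect_equal(w$ideal_concentrations[["OH-"]], 1e-7)
  # the singly-ionized fraction peaks midway between the pKa values
  mid <- (4.2 + 5.6) / 2
  f <- ideal_speciation(c(mid - 0.3, mid, mid + 0.3))
  expect_true(which.max(f[["HSuA-"]]) == 2)
  # infeasible target
  expect_error(constants_from_reservoir(pH = 3, c_salt = 0), "infeasible")
})

test_that("calibrated reservoir composition is intensive and matches targets", {
  set.seed(44)
  tab <- default_species_table()
  cons <- constants_from_reservoir(pH = 7, c_salt = 0.12)
  run_box <- function(L) {
    st <- build_reservoir_box(L, cons$ideal_concentrations,
                              species_table = tab)
    calibrate_reservoir(st, cons$reactions, n_cycles = 60,
                        mc_attempts = 400, interactions = "none")
  }
  r1 <- run_box(12)
  cNa <- r1$concentrations$mean[r1$concentrations$species == "Na+"]
  se1 <- r1$concentrations$stderr[r1$concentrations$species == "Na+"]
  expect_lt(abs(cNa - 0.12), 4 * se1 + 0.012)
  # doubling the volume leaves concentrations unchanged within error
  r2 <- run_box(15.12) # 2x volume
  cNa2 <- r2$concentrations$mean[r2$concentrations$species == "Na+"]
  se2 <- r2$concentrations$stderr[r2$concentrations$species == "Na+"]
  expect_lt(abs(cNa - cNa2), 4 * (se1 + se2) + 0.012)
})

test_that("interactions shift the realised salt concentration upward", {
  # Debye-Hueckel activity lowering favours insertions, so the measured
  # concentration exceeds the ideal target when electrostatics is on
  set.seed(45)
  tab <- default_species_table()
  cons <- constants_from_reservoir(pH = 7, c_salt = 0.15)
  st <- build_reservoir_box(10, cons$ideal_concentrations,
                            lB = nm_to_reduced(bjerrum_from_permittivity(78)),
                            species_table = tab)
  res <- calibrate_reservoir(st, cons$reactions, n_cycles = 40,
                             mc_attempts = 60, md_steps = 100,
                             interactions = "full")
  expect_gt(res$c_salt, 0.15)
})

test_that("two boxes sharing one constant set equalise mass-action products", {
  set.seed(46)
  tab <- default_species_table()
  cons <- constants_from_reservoir(pH = 7, c_salt = 0.1)
  prods <- vapply(c(10, 13), function(L) {
    st <- build_reservoir_box(L, cons$ideal_concentrations,
                              species_table = tab)
    out <- run_grxmc(st, cons$reactions, 4e4, interactions = "none",
                     sample_every = 10)
    V <- L^3
    mean(out$counts[, "Na+"] * out$counts[, "Cl-"]) /
      (V * molar_to_reduced(1))^2
  }, numeric(1))
  expect_equal(prods[1], prods[2], tolerance = 0.15)
})
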