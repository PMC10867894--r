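#' Define one grand-reaction Monte Carlo reaction
#'
#' A reaction is a signed stoichiometry over species names (negative =
#' consumed) together with a dimensionless equilibrium constant referred to
#' the reference concentration \eqn{c^\circ = 1} mol/L. The stoichiometry
#' must be charge-neutral so every accepted move preserves electroneutrality
#' exactly, and must not touch polymer backbone species.
#'
#' @param stoich named numeric vector of stoichiometric coefficients.
#' @param K_gamma dimensionless equilibrium constant.
#' @param label human-readable label.
#' @param species_table registry used to validate charges.
#' @return object of class `reaction_spec`.
#' @export
reaction_spec <- function(stoich, K_gamma, label = NULL,
                          species_table = default_species_table()) {
  stopifnot(length(stoich) >= 1, all(stoich == round(stoich)),
            K_gamma > 0, !is.null(names(stoich)))
  if (all(stoich == 0)) stop("reaction changes no species")
  miss <- setdiff(names(stoich), species_table$name)
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  row <- match(names(stoich), species_table$name)
  if (any(species_table$monomer[row] & stoich != 0))
    stop("monomers are not exchangeable: reaction touches a backbone species")
  zq <- sum(species_table$z[row] * stoich)
  if (zq != 0) stop("reaction stoichiometry is not charge-neutral (dz = ",
                    zq, ")")
  structure(list(stoich = stoich, K_gamma = K_gamma,
                 label = if (is.null(label)) paste(names(stoich), stoich,
                                                   collapse = " ") else label),
            class = "reaction_spec")
}

#' Reaction-move acceptance probability
#'
#' \eqn{\min[1,\; \Gamma^{\xi} \prod_i \frac{N_i^0!}{(N_i^0+\xi\nu_i)!}
#' (V c^\circ)^{\xi \nu_i} e^{-\beta \Delta E}]}, evaluated in log space via
#' `lgamma`. Proposals that would drive any particle count negative return
#' probability 0.
#'
#' @param counts named integer vector, particles per species before the move.
#' @param reaction a [reaction_spec()].
#' @param xi extent of reaction, +1 (forward) or -1 (backward).
#' @param dE energy change (kBT) of the trial move.
#' @param V box volume, reduced units.
#' @param c0 reference concentration in reduced number density (defaults to
#'   1 mol/L converted).
#' @return acceptance probability in \[0, 1\].
#' @export
acceptance_probability <- function(counts, reaction, xi, dE, V,
                                   c0 = molar_to_reduced(1)) {
  stopifnot(xi %in% c(-1, 1))
  nu <- reaction$stoich
  n0 <- counts[names(nu)]
  if (any(is.na(n0))) stop("counts is missing species named in the reaction")
  n1 <- n0 + xi * nu
  if (any(n1 < 0)) return(0)
  if (!is.finite(dE)) return(if (dE > 0) 0 else 1)
  lacc <- xi * log(reaction$K_gamma) +
    sum(lgamma(n0 + 1) - lgamma(n1 + 1) + xi * nu * log(V * c0)) - dE
  min(1, exp(lacc))
}

# particle counts per species-name for a state
species_counts <- function(state) {
  tab <- tabulate(state$species_idx, nbins = nrow(state$species_table))
  stats::setNames(tab, state$species_table$name)
}

# apply one reaction with extent xi to the state: convert in place where a
# consumed particle can become a produced one, delete the rest, insert the
# remainder at uniformly random positions. Returns NULL if counts forbid it.
.apply_reaction <- function(state, reaction, xi) {
  nu <- reaction$stoich * xi
  names(nu) <- names(reaction$stoich)
  cons <- nu[nu < 0]
  prod <- nu[nu > 0]
  counts <- species_counts(state)
  if (any(counts[names(cons)] < -cons)) return(NULL)

  # uniformly chosen particles of each consumed species
  del_rows <- integer(0)
  for (s in names(cons)) {
    sp <- match(s, state$species_table$name)
    rows <- which(state$species_idx == sp)
    del_rows <- c(del_rows, rows[sample.int(length(rows), -cons[[s]])])
  }
  ins_species <- rep(match(names(prod), state$species_table$name), prod)

  n_conv <- min(length(del_rows), length(ins_species))
  if (n_conv > 0) { # identity changes in place
    state$species_idx[del_rows[seq_len(n_conv)]] <- ins_species[seq_len(n_conv)]
  }
  if (length(del_rows) > n_conv)
    state <- state_remove_particles(state, del_rows[setdiff(seq_along(del_rows),
                                                            seq_len(n_conv))])
  if (length(ins_species) > n_conv) {
    extra <- ins_species[setdiff(seq_along(ins_species), seq_len(n_conv))]
    pos <- matrix(stats::runif(3 * length(extra), 0, state$L),
                  length(extra), 3)
    for (k in seq_along(extra))
      state <- state_add_particles(state, extra[k], pos[k, , drop = FALSE])
  }
  state
}

#' Run grand-reaction Monte Carlo moves
#'
#' Each attempt selects one reaction uniformly at random, then a direction
#' (forward/backward) with equal probability, proposes the corresponding
#' insertions, deletions and in-place identity changes, and accepts with
#' [acceptance_probability()]. Inserted particles receive Maxwell
#' velocities at kBT = 1. With `interactions = "none"` the energy change is
#' zero (ideal-gas sampling); with `"full"` it is recomputed from the
#' state's interaction model.
#'
#' @param state a [system_state()].
#' @param reactions list of [reaction_spec()].
#' @param n_attempts number of Monte Carlo attempts.
#' @param interactions `"full"` or `"none"`.
#' @param sample_every record species counts every this many attempts.
#' @return list with the updated `state`, a `counts` matrix (samples x
#'   species), and the acceptance fraction `acc_rate`.
#' @export
run_grxmc <- function(state, reactions, n_attempts,
                      interactions = c("full", "none"), sample_every = 10L) {
  interactions <- match.arg(interactions)
  V <- state$L^3
  nsamp <- if (sample_every > 0) n_attempts %/% sample_every else 0
  counts_mat <- matrix(0L, nsamp, nrow(state$species_table),
                       dimnames = list(NULL, state$species_table$name))
  isamp <- 0L
  accepted <- 0L
  e_old <- if (interactions == "full") total_energy(state)$total else 0
  for (att in seq_len(n_attempts)) {
    r <- reactions[[sample.int(length(reactions), 1)]]
    xi <- if (stats::runif(1) < 0.5) 1 else -1
    trial <- .apply_reaction(state, r, xi)
    if (!is.null(trial)) {
      dE <- if (interactions == "full") total_energy(trial)$total - e_old else 0
      p <- acceptance_probability(species_counts(state), r, xi, dE, V)
      if (stats::runif(1) < p) {
        state <- trial
        if (interactions == "full") e_old <- e_old + dE
        accepted <- accepted + 1L
      }
    }
    if (sample_every > 0 && att %% sample_every == 0) {
      isamp <- isamp + 1L
      counts_mat[isamp, ] <- tabulate(state$species_idx,
                                      nbins = nrow(state$species_table))
    }
  }
  list(state = state, counts = counts_mat, acc_rate = accepted / n_attempts)
}

#' Equilibrium constants from reservoir targets
#'
#' Maps reservoir targets (pH, NaCl concentration, total diprotic-acid
#' concentration, optional divalent-salt concentration) to the set of
#' dimensionless reaction constants at the ideal-gas level via mass action.
#' The four ion-pair insertion constants are not independent: the water
#' ionic product is fixed and the electroneutrality of the reservoir fixes
#' one of the remaining three, so the returned set satisfies
#' \eqn{\Gamma_{NaCl}\Gamma_w = \Gamma_{HCl}\Gamma_{NaOH}} by construction.
#' The acid-exchange constants are composed from the acidity constants and
#' the reservoir acid speciation, closing all thermodynamic cycles over the
#' reaction network. The exact concentrations realised in an interacting
#' reservoir differ from the ideal targets; measure them with
#' [calibrate_reservoir()].
#'
#' @param pH reservoir pH (concentration scale).
#' @param c_salt NaCl concentration, mol/L.
#' @param c_acid total diprotic-acid concentration, mol/L (0 disables the
#'   acid reactions).
#' @param c_divalent divalent salt (MCl2) concentration, mol/L (0 disables).
#' @param pKa1,pKa2 acidity constants of the diprotic acid.
#' @param pKw water ionic product.
#' @param species_table species registry.
#' @return list with `reactions` (list of [reaction_spec()]) and
#'   `ideal_concentrations` (named, mol/L).
#' @export
constants_from_reservoir <- function(pH, c_salt, c_acid = 0, c_divalent = 0,
                                     pKa1 = 4.2, pKa2 = 5.6, pKw = 14,
                                     species_table = default_species_table()) {
  stopifnot(c_salt >= 0, c_acid >= 0, c_divalent >= 0)
  cH <- 10^(-pH)
  cOH <- 10^(pH - pKw)
  f <- ideal_speciation(pH, pKa1, pKa2)
  anion_charge <- (f[["HSuA-"]] + 2 * f[["SuA2-"]]) * c_acid
  delta <- cOH - cH + anion_charge # NaOH (>0) or HCl (<0) needed
  cNa <- c_salt + max(0, delta)
  cCl <- c_salt + 2 * c_divalent + max(0, -delta)
  conc <- c("Na+" = cNa, "Cl-" = cCl, "H+" = cH, "OH-" = cOH,
            "M2+" = c_divalent,
            "H2SuA" = f[["H2SuA"]] * c_acid,
            "HSuA-" = f[["HSuA-"]] * c_acid,
            "SuA2-" = f[["SuA2-"]] * c_acid)
  if (cNa <= 0 || cCl <= 0)
    stop("infeasible reservoir: implied Na+ or Cl- concentration is not positive")
  rx <- list(
    reaction_spec(c("Na+" = 1, "Cl-" = 1), cNa * cCl, "NaCl insertion",
                  species_table),
    reaction_spec(c("H+" = 1, "Cl-" = 1), cH * cCl, "HCl insertion",
                  species_table),
    reaction_spec(c("Na+" = 1, "OH-" = 1), cNa * cOH, "NaOH insertion",
                  species_table),
    reaction_spec(c("H+" = 1, "OH-" = 1), cH * cOH, "water autoionization",
                  species_table)
  )
  if (c_divalent > 0)
    rx <- c(rx, list(reaction_spec(c("M2+" = 1, "Cl-" = 2), c_divalent * cCl^2,
                                   "MCl2 insertion", species_table)))
  if (c_acid > 0) {
    rx <- c(rx, list(
      reaction_spec(c("H2SuA" = -1, "H+" = 1, "HSuA-" = 1), 10^(-pKa1),
                    "first deprotonation", species_table),
      reaction_spec(c("HSuA-" = -1, "H+" = 1, "SuA2-" = 1), 10^(-pKa2),
                    "second deprotonation", species_table),
      reaction_spec(c("H2SuA" = 1), conc[["H2SuA"]], "H2SuA insertion",
                    species_table),
      reaction_spec(c("Na+" = 1, "HSuA-" = 1), cNa * conc[["HSuA-"]],
                    "NaHSuA insertion", species_table),
      reaction_spec(c("Na+" = 2, "SuA2-" = 1), cNa^2 * conc[["SuA2-"]],
                    "Na2SuA insertion", species_table)
    ))
  }
  list(reactions = rx, ideal_concentrations = conc)
}

#' Initialize a polymer-free reservoir box
#'
#' Particle numbers start at the rounded ideal targets (charge balanced by
#' construction of the reservoir mapping; any rounding remainder is fixed by
#' adding counter-charges).
#'
#' @param L box edge, reduced units.
#' @param ideal_concentrations named vector (mol/L) as returned by
#'   [constants_from_reservoir()].
#' @param lB Bjerrum length of the supernatant.
#' @param species_table species registry.
#' @export
build_reservoir_box <- function(L, ideal_concentrations,
                                lB = nm_to_reduced(bjerrum_from_permittivity(78)),
                                species_table = default_species_table()) {
  V <- L^3
  n <- round(molar_to_reduced(ideal_concentrations) * V)
  n <- n[n > 0]
  idx <- unlist(lapply(names(n), function(s)
    rep(match(s, species_table$name), n[[s]])))
  if (is.null(idx)) idx <- integer(0)
  # repair any rounding-induced net charge with Na+ / Cl-
  q <- sum(species_table$z[idx])
  if (q > 0) idx <- c(idx, rep(match("Cl-", species_table$name), q))
  if (q < 0) idx <- c(idx, rep(match("Na+", species_table$name), -q))
  pos <- matrix(stats::runif(3 * length(idx), 0, L), length(idx), 3)
  system_state(L, pos, idx, species_table, topology = list(), lB = lB)
}

#' Measure the realised composition of a reservoir
#'
#' Runs grand-reaction sampling (optionally interleaved with Langevin
#' dynamics when interactions are on) and reports time-averaged
#' concentrations with block standard errors, the pH on the concentration
#' scale, the salt concentration and the ionic strength. A drift flag
#' compares the first and second half of the series.
#'
#' @param state a reservoir [system_state()] (no polymers).
#' @param reactions reaction set from [constants_from_reservoir()].
#' @param n_cycles number of MD/MC cycles.
#' @param mc_attempts reaction attempts per cycle.
#' @param md_steps Langevin steps per cycle (ignored for ideal sampling).
#' @param interactions `"full"` or `"none"`.
#' @param n_blocks blocks for error estimation.
#' @return list with `concentrations` (data frame: species, mean mol/L,
#'   stderr), `pH`, `c_salt`, `ionic_strength`, `drift_flag`, final `state`.
#' @export
calibrate_reservoir <- function(state, reactions, n_cycles = 50,
                                mc_attempts = 200, md_steps = 200,
                                interactions = c("full", "none"),
                                n_blocks = 5) {
  interactions <- match.arg(interactions)
  run <- run_two_phase_cycles(state, reactions, n_cycles, mc_attempts,
                              md_steps, interactions)
  summarize_composition(run, state, n_blocks = n_blocks)
}

# shared MD/MC cycle driver; returns per-cycle species counts (+pressures)
run_two_phase_cycles <- function(state, reactions, n_cycles, mc_attempts,
                                 md_steps, interactions,
                                 sample_pressure = FALSE,
                                 langevin = langevin_params()) {
  counts <- matrix(0L, n_cycles, nrow(state$species_table),
                   dimnames = list(NULL, state$species_table$name))
  pressures <- numeric(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    if (interactions == "full" && md_steps > 0) {
      lp <- langevin_params(langevin$gamma, langevin$dt, md_steps)
      state <- run_langevin(state, lp, sample_every = 0L)$state
    }
    mc <- run_grxmc(state, reactions, mc_attempts, interactions,
                    sample_every = 0L)
    state <- mc$state
    counts[cyc, ] <- tabulate(state$species_idx,
                              nbins = nrow(state$species_table))
    if (sample_pressure)
      pressures[cyc] <- if (interactions == "full") virial_pressure(state)
                        else nrow(state$positions) / state$L^3
  }
  list(state = state, counts = counts,
       pressures = if (sample_pressure) pressures else NULL)
}

# block-averaged concentrations and derived reservoir observables
summarize_composition <- function(run, state, n_blocks = 5, discard = 0.2) {
  counts <- run$counts
  keep <- seq(floor(nrow(counts) * discard) + 1, nrow(counts))
  counts <- counts[keep, , drop = FALSE]
  V <- state$L^3
  conc <- reduced_to_molar(counts / V)
  blk <- cut(seq_len(nrow(conc)), n_blocks, labels = FALSE)
  means <- colMeans(conc)
  se <- apply(conc, 2, function(x) {
    bm <- tapply(x, blk, mean)
    stats::sd(bm) / sqrt(length(bm))
  })
  half <- nrow(conc) %/% 2
  drift <- abs(colMeans(conc[seq_len(half), , drop = FALSE]) -
               colMeans(conc[-seq_len(half), , drop = FALSE]))
  drift_flag <- any(drift > 4 * (se + 1e-15) & means > 0)
  z <- run$state$species_table$z
  list(concentrations = data.frame(species = names(means), mean = means,
                                   stderr = se,
                                   exchangeable = run$state$species_table$exchangeable,
                                   row.names = NULL),
       pH = -log10(means[["H+"]]),
       c_salt = min(means[["Na+"]], means[["Cl-"]]),
       ionic_strength = 0.5 * sum(means * z^2),
       drift_flag = drift_flag, state = run$state,
       counts = counts, pressures = run$pressures)
}

#' Simulate one phase coupled to the reservoir
#'
#' The production pattern of the method: Langevin dynamics interleaved with
#' bursts of grand-reaction Monte Carlo attempts (the published cadence is
#' 500 attempts every 1e4 steps; both are configurable), recording species
#' counts and optionally the virial pressure each cycle.
#'
#' @param state a [system_state()] (PEC box with polymers, or polymer-free
#'   supernatant box).
#' @param reactions shared reaction-constant set.
#' @param n_cycles MD+MC cycles.
#' @param md_steps Langevin steps per cycle.
#' @param mc_attempts reaction attempts per cycle.
#' @param interactions `"full"` or `"none"`.
#' @param sample_pressure record the virial pressure per cycle?
#' @param langevin Langevin parameters (friction, time step).
#' @param n_blocks blocks for error estimation.
#' @return composition summary as in [calibrate_reservoir()], plus
#'   `pressures` when requested.
#' @export
run_phase <- function(state, reactions, n_cycles = 50, md_steps = 200,
                      mc_attempts = 200, interactions = c("full", "none"),
                      sample_pressure = FALSE, langevin = langevin_params(),
                      n_blocks = 5) {
  interactions <- match.arg(interactions)
  run <- run_two_phase_cycles(state, reactions, n_cycles, mc_attempts,
                              md_steps, interactions, sample_pressure,
                              langevin)
  summarize_composition(run, state, n_blocks = n_blocks)
}
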