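#' Simulation state of one phase
#'
#' A cubic periodic box holding particle positions, velocities, species
#' indices, bonded topology (list of chains, each an ordered vector of
#' particle indices) and the phase's Bjerrum length. Polymer beads must come
#' first in the particle arrays; reaction moves only ever append or remove
#' trailing (non-monomer) particles, so chain topology indices stay valid.
#'
#' @param L box edge, reduced units.
#' @param positions N x 3 matrix, reduced coordinates.
#' @param species_idx integer vector, row index into `species_table`.
#' @param species_table data frame from [default_species_table()].
#' @param topology list of integer vectors, one per chain.
#' @param lB Bjerrum length of the phase, reduced units.
#' @param velocities N x 3 matrix; Maxwell-distributed at kBT = 1 if omitted.
#' @param bond bond parameters, see [bond_params()].
#' @param exclude_bonded_wca if `TRUE`, bonded nearest neighbours interact
#'   through the harmonic bond only. The default keeps the nonbonded pair
#'   term for bonded pairs as well, which reproduces the published mean bond
#'   length and its spread.
#' @param ewald_accuracy target relative accuracy of the Ewald sum.
#' @param cutoff_factor passed to [pair_table()].
#' @return object of class `system_state`.
#' @export
system_state <- function(L, positions, species_idx, species_table,
                         topology = list(), lB = 0, velocities = NULL,
                         bond = bond_params(), exclude_bonded_wca = FALSE,
                         ewald_accuracy = 1e-3, cutoff_factor = 2.5) {
  positions <- as.matrix(positions)
  stopifnot(L > 0, ncol(positions) == 3,
            length(species_idx) == nrow(positions),
            all(species_idx >= 1), all(species_idx <= nrow(species_table)))
  if (is.null(velocities)) velocities <- maxwell_velocities(nrow(positions))
  bonds <- topology_bonds(topology)
  if (length(bonds) && (any(bonds < 1) || any(bonds > nrow(positions))))
    stop("topology refers to non-existent particles")
  state <- structure(list(
    L = L, positions = positions, velocities = as.matrix(velocities),
    species_idx = as.integer(species_idx), species_table = species_table,
    topology = topology, lB = lB, bond = bond,
    exclude_bonded_wca = exclude_bonded_wca,
    ewald_accuracy = ewald_accuracy,
    pairs = pair_table(species_table, cutoff_factor)
  ), class = "system_state")
  state
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> N = %d, L = %.3f, lB = %.3f, %d chain(s)\n",
              nrow(x$positions), x$L, x$lB, length(x$topology)))
  tab <- table(x$species_table$name[x$species_idx])
  print(tab)
  invisible(x)
}

# consecutive pairs along every chain, as an nb x 2 matrix (1-based)
topology_bonds <- function(topology) {
  if (!length(topology)) return(matrix(integer(), 0, 2))
  do.call(rbind, lapply(topology, function(ch) {
    if (length(ch) < 2) return(matrix(integer(), 0, 2))
    cbind(ch[-length(ch)], ch[-1])
  }))
}

#' Maxwell-Boltzmann velocities at kBT = 1, m = 1
#' @param n number of particles.
#' @export
maxwell_velocities <- function(n) matrix(stats::rnorm(3 * n), n, 3)

#' Total charge of the state (must vanish for electrostatics)
#' @param state a [system_state()].
#' @export
total_charge <- function(state) {
  sum(state$species_table$z[state$species_idx])
}

#' Tune Ewald parameters to a target relative accuracy
#'
#' Classic error estimates: the splitting parameter is chosen so the
#' real-space term truncated at `rcut` and the reciprocal sum truncated at
#' `nmax` shells both fall below the target. The achieved accuracy is
#' asserted against a two-charge probe in the test-suite.
#'
#' @param L box edge.
#' @param accuracy target relative accuracy (default 1e-3).
#' @param rcut real-space cutoff; defaults to just under L/2.
#' @return list with `alpha`, `rcut`, `nmax`.
#' @export
ewald_params <- function(L, accuracy = 1e-3, rcut = 0.499 * L) {
  stopifnot(accuracy > 0, accuracy < 1, rcut <= L / 2)
  x <- -stats::qnorm(accuracy / 2) / sqrt(2) # erfc(x) = accuracy
  alpha <- 1.1 * x / rcut
  kcut <- 2 * alpha * sqrt(log(1 / accuracy)) * 1.1
  nmax <- max(3L, as.integer(ceiling(kcut * L / (2 * pi))))
  list(alpha = alpha, rcut = rcut, nmax = nmax)
}

# flatten a state into the argument list the C++ kernels expect
.cpp_model <- function(state) {
  ew <- ewald_params(state$L, state$ewald_accuracy)
  bonds <- topology_bonds(state$topology)
  list(L = state$L, lB = state$lB, z = as.numeric(state$species_table$z),
       sigma = state$pairs$sigma, lam = state$pairs$lam,
       rcut = state$pairs$rcut, ushift = state$pairs$ushift,
       bonds = matrix(as.integer(bonds - 1L), ncol = 2),
       kbond = state$bond$k_bond, r0 = state$bond$r0,
       exclude_bonded_wca = state$exclude_bonded_wca,
       ewald_alpha = ew$alpha, ewald_rcut = ew$rcut, ewald_nmax = ew$nmax)
}

.check_neutral <- function(state) {
  z <- state$species_table$z[state$species_idx]
  if (any(z != 0) && sum(z) != 0)
    stop("electrostatics refused: system is not charge-neutral (total z = ",
         sum(z), ")")
}

#' Total potential energy with breakdown
#'
#' Bonded, short-range (WCA) and electrostatic contributions. Electrostatics
#' is evaluated by classic Ewald summation with conducting (tinfoil)
#' boundary conditions, parameters auto-tuned to the state's accuracy
#' target; a non-neutral charged system is refused.
#'
#' @param state a [system_state()].
#' @return list with `bonded`, `short_range`, `electrostatic`, `total` (kBT).
#' @export
total_energy <- function(state) {
  .check_neutral(state)
  cpp_energy(state$positions, state$species_idx - 1L, .cpp_model(state))
}

#' Forces on all particles
#' @inheritParams total_energy
#' @return N x 3 matrix, kBT per reduced length.
#' @export
forces <- function(state) {
  .check_neutral(state)
  cpp_forces(state$positions, state$species_idx - 1L, .cpp_model(state))
}

#' Instantaneous virial pressure
#'
#' Ideal term \eqn{N k_B T / V} plus short-range, bonded and electrostatic
#' virial contributions; the reciprocal-space Ewald virial uses the analytic
#' volume derivative of the truncated sum.
#'
#' @inheritParams total_energy
#' @param breakdown return the individual contributions too?
#' @return pressure in reduced units, or a list if `breakdown = TRUE`.
#' @export
virial_pressure <- function(state, breakdown = FALSE) {
  .check_neutral(state)
  p <- cpp_pressure(state$positions, state$species_idx - 1L, .cpp_model(state))
  if (breakdown) p else p$total
}

#' Langevin dynamics parameters
#' @param gamma friction coefficient, reduced units.
#' @param dt integration time step (default 0.01 tau).
#' @param steps number of steps.
#' @export
langevin_params <- function(gamma = 1, dt = 0.01, steps = 10000L) {
  stopifnot(gamma >= 0, dt > 0, steps >= 1)
  list(gamma = gamma, dt = dt, steps = as.integer(steps))
}

#' Propagate a state by Langevin dynamics
#'
#' BAOAB splitting of the Langevin equation at kBT = 1; `gamma = 0` with
#' `noise = FALSE` reduces to plain velocity Verlet (used by the integrator
#' order checks). Randomness is drawn from R's RNG stream, so runs are
#' reproducible under `set.seed()`.
#'
#' @param state a [system_state()].
#' @param params a [langevin_params()].
#' @param sample_every sampling interval in steps (0 disables sampling).
#' @param sample_pressure also record the virial pressure at each sample?
#' @param noise include the stochastic force?
#' @return list with the updated `state` and a `trajectory` (class
#'   `pec_trajectory`) holding frames, times, an energy table and optional
#'   pressures.
#' @export
run_langevin <- function(state, params = langevin_params(),
                         sample_every = 100L, sample_pressure = FALSE,
                         noise = TRUE) {
  .check_neutral(state)
  out <- cpp_run_langevin(state$positions, state$velocities,
                          state$species_idx - 1L, .cpp_model(state),
                          params$dt, params$gamma, params$steps,
                          as.integer(sample_every), noise, sample_pressure)
  state$positions <- out$pos
  state$velocities <- out$vel
  energies <- out$energies
  colnames(energies) <- c("bonded", "short_range", "electrostatic", "kinetic")
  traj <- structure(list(
    frames = out$frames, times = out$times, energies = energies,
    pressures = if (sample_pressure) out$pressures else NULL,
    L = state$L, species_idx = state$species_idx,
    species_table = state$species_table, topology = state$topology
  ), class = "pec_trajectory")
  list(state = state, trajectory = traj)
}

#' Wrap positions into the primary box [0, L)
#' @inheritParams total_energy
#' @export
wrap_positions <- function(state) {
  state$positions <- state$positions %% state$L
  state
}

#' Mean bond length of a trajectory
#'
#' Mean and standard deviation of instantaneous bond lengths over all frames
#' and bonds, with the standard error of the mean estimated by block
#' averaging over frames.
#'
#' @param trajectory a `pec_trajectory` with at least one bond.
#' @param n_blocks blocks for the standard-error estimate.
#' @return list with `mean`, `sd`, `stderr` (reduced length units).
#' @export
mean_bond_length <- function(trajectory, n_blocks = 5) {
  bonds <- topology_bonds(trajectory$topology)
  if (!nrow(bonds)) stop("trajectory has no bonds")
  L <- trajectory$L
  per_frame <- vapply(trajectory$frames, function(p) {
    d <- p[bonds[, 1], , drop = FALSE] - p[bonds[, 2], , drop = FALSE]
    d <- d - L * round(d / L)
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  all_b <- unlist(lapply(trajectory$frames, function(p) {
    d <- p[bonds[, 1], , drop = FALSE] - p[bonds[, 2], , drop = FALSE]
    d <- d - L * round(d / L)
    sqrt(rowSums(d^2))
  }))
  blocks <- split(per_frame, cut(seq_along(per_frame), n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  list(mean = mean(all_b), sd = stats::sd(all_b),
       stderr = stats::sd(bm) / sqrt(length(bm)))
}

#' Box edge that realizes a target monomer volume fraction
#'
#' Inverts the volume-fraction definition \eqn{\phi = N (\pi/6) \sigma^3 /
#' L^3}.
#'
#' @param n_monomers number of monomer beads.
#' @param sigma_mon monomer diameter, reduced.
#' @param phi target volume fraction.
#' @export
box_edge_for_phi <- function(n_monomers, sigma_mon, phi) {
  stopifnot(phi > 0, phi < 1)
  (n_monomers * (pi / 6) * sigma_mon^3 / phi)^(1 / 3)
}

#' Build a single linear chain in a large box
#'
#' Convenience builder for engine tests and the bond-length benchmark: one
#' chain of `n` beads, extended along z at the rest length, in a box large
#' enough that the chain never interacts with its periodic images.
#'
#' @param n number of beads.
#' @param charged alternate A-/C+ beads (neutral overall) instead of neutral
#'   beads.
#' @param sigma_mon bead diameter, reduced units.
#' @param lB Bjerrum length (only relevant when `charged = TRUE`).
#' @param bond bond parameters.
#' @export
build_single_chain <- function(n, charged = FALSE, sigma_mon = 1.2, lB = 0,
                               bond = bond_params()) {
  tab <- if (charged) default_species_table(sigma_mon = sigma_mon) else
    species("M0", 0, sigma_mon, 0, exchangeable = FALSE, monomer = TRUE)
  idx <- if (charged) rep_len(c(1L, 2L), n) else rep(1L, n)
  L <- (n + 2) * bond$r0 * 2
  pos <- cbind(L / 2, L / 2, bond$r0 * seq_len(n))
  system_state(L, pos, idx, tab, topology = list(seq_len(n)), lB = lB,
               bond = bond)
}

#' Initialize a PEC box at a target polymer volume fraction
#'
#' Polymers start as fully extended rods regularly distributed on a
#' primitive cubic lattice in a dilute box; the box is then iteratively
#' compressed by `delta_L` (0.7 sigma) per step, rescaling all coordinates
#' affinely and relaxing with Langevin dynamics between compressions, until
#' the monomer volume fraction reaches `target_phi` within one compression
#' step.
#'
#' @param n_chains_per_species number of polyanions = number of polycations.
#' @param chain_length beads per chain.
#' @param target_phi target monomer volume fraction.
#' @param species_table species registry (first two rows must be the two
#'   monomer species).
#' @param lB Bjerrum length of the phase.
#' @param bond bond parameters.
#' @param relax_steps Langevin steps between compressions (the production
#'   protocol uses 1e5; desk-scale tests use far fewer).
#' @param delta_L compression decrement per iteration, reduced units.
#' @param gamma,dt Langevin parameters for the relaxation runs.
#' @param ewald_accuracy accuracy used during preparation (the published
#'   protocol prepares at 1e-2 and retunes afterwards).
#' @param verbose print compression progress?
#' @return a [system_state()] at the target volume fraction.
#' @export
build_initial_pec <- function(n_chains_per_species, chain_length, target_phi,
                              species_table = default_species_table(),
                              lB = nm_to_reduced(bjerrum_from_permittivity(62)),
                              bond = bond_params(), relax_steps = 1000L,
                              delta_L = 0.7, gamma = 1, dt = 0.01,
                              ewald_accuracy = 1e-2, verbose = FALSE) {
  n_chains <- 2L * n_chains_per_species
  n_mon <- n_chains * chain_length
  sigma_mon <- species_table$diameter[1]
  L_final <- box_edge_for_phi(n_mon, sigma_mon, target_phi)
  rod <- (chain_length - 1) * bond$r0
  # fully extended rods along z, one per site of a square lattice in the
  # xy-plane (regular, overlap-free even when the rod spans the box)
  if (target_phi > 0.45)
    stop("target_phi out of feasible range: dense sphere packings above ",
         "phi = 0.45 cannot be prepared without unrecoverable overlap")
  ngrid <- ceiling(sqrt(n_chains))
  # start at the larger of the overlap-free lattice and the final box (a
  # dilute target needs no compression at all)
  L0 <- max(rod + 2 * sigma_mon, ngrid * 2 * sigma_mon, L_final)

  sites <- expand.grid(x = seq_len(ngrid),
                       y = seq_len(ngrid))[seq_len(n_chains), ]
  spacing <- L0 / ngrid
  pos <- matrix(0, n_mon, 3)
  idx <- integer(n_mon)
  topo <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    rows <- ((c - 1) * chain_length + 1):(c * chain_length)
    pos[rows, 1] <- (sites$x[c] - 0.5) * spacing
    pos[rows, 2] <- (sites$y[c] - 0.5) * spacing
    pos[rows, 3] <- (L0 - rod) / 2 + bond$r0 * (seq_len(chain_length) - 1)
    idx[rows] <- if (c %% 2 == 1) 1L else 2L
    topo[[c]] <- rows
  }
  state <- system_state(L0, pos, idx, species_table, topology = topo, lB = lB,
                        bond = bond, ewald_accuracy = ewald_accuracy)
  state <- run_langevin(state, langevin_params(gamma, dt, relax_steps),
                        sample_every = 0L)$state
  while (state$L - delta_L > L_final) {
    fac <- (state$L - delta_L) / state$L
    state$L <- state$L - delta_L
    state$positions <- state$positions * fac
    state <- run_langevin(state, langevin_params(gamma, dt, relax_steps),
                          sample_every = 0L)$state
    if (verbose)
      message(sprintf("L = %.2f, phi = %.4f", state$L,
                      volume_fraction(state, "monomers")))
  }
  # final exact step to the target edge
  fac <- L_final / state$L
  state$L <- L_final
  state$positions <- state$positions * fac
  state <- run_langevin(state, langevin_params(gamma, dt, relax_steps),
                        sample_every = 0L)$state
  wrap_positions(state)
}

# --- particle bookkeeping used by the reaction moves -----------------------

# append particles of one species at given positions
state_add_particles <- function(state, sp_idx, positions) {
  n_new <- nrow(positions)
  state$positions <- rbind(state$positions, positions)
  state$velocities <- rbind(state$velocities, maxwell_velocities(n_new))
  state$species_idx <- c(state$species_idx, rep(as.integer(sp_idx), n_new))
  state
}

# remove particles by row index; monomers are not exchangeable
state_remove_particles <- function(state, rows) {
  if (any(state$species_table$monomer[state$species_idx[rows]]))
    stop("attempt to delete a polymer backbone particle")
  state$positions <- state$positions[-rows, , drop = FALSE]
  state$velocities <- state$velocities[-rows, , drop = FALSE]
  state$species_idx <- state$species_idx[-rows]
  state
}
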