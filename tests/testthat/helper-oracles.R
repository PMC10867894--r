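# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct image summation for periodic Coulomb
# energies, trapezoid quadrature for B2, and closed forms where available.

# Direct summation of the periodic Coulomb energy over explicit images in
# cube order, converted to tinfoil boundary conditions by removing the
# surface dipole term 2*pi*lB*|M|^2/(3V).
direct_coulomb_sum <- function(pos, q, L, lB, nimg = 8) {
  N <- nrow(pos)
  imgs <- as.matrix(expand.grid(-nimg:nimg, -nimg:nimg, -nimg:nimg)) * L
  E <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (q[i] == 0 || q[j] == 0) next
    d <- sweep(imgs, 2, pos[j, ] - pos[i, ], "+")
    r <- sqrt(rowSums(d^2))
    if (i == j) r <- r[r > 1e-12] # skip the n = 0 self term
    E <- E + 0.5 * q[i] * q[j] * lB * sum(1 / r)
  }
  M <- colSums(pos * q)
  E - 2 * pi * lB * sum(M^2) / (3 * L^3)
}

# fixed-grid trapezoid oracle for the second virial coefficient
b2_trapezoid <- function(lam, sigma, rcut = 2.5 * sigma, n = 40000) {
  r <- seq(1e-6, rcut, length.out = n)
  u <- wca_energy(r, sigma, lam, rcut)
  f <- (exp(-u) - 1) * r^2
  -2 * pi * sum((f[-1] + f[-n]) / 2 * diff(r))
}

# Boltzmann quadrature for the bond-length distribution of an isolated dimer
dimer_bond_moments <- function(k_bond, r0, with_wca = FALSE, sigma = 1.2,
                               rcut = 2.5) {
  U <- function(r) {
    u <- 0.5 * k_bond * (r - r0)^2
    if (with_wca) u <- u + wca_energy(r, sigma, 0, rcut)
    u
  }
  z0 <- stats::integrate(function(r) r^2 * exp(-U(r)), 0, r0 + 1)$value
  z1 <- stats::integrate(function(r) r^3 * exp(-U(r)), 0, r0 + 1)$value
  z2 <- stats::integrate(function(r) r^4 * exp(-U(r)), 0, r0 + 1)$value
  list(mean = z1 / z0, var = z2 / z0 - (z1 / z0)^2)
}

# a truly non-interacting bead: neutral, with a vanishing diameter so the
# repulsive core is never reached (ideal-gas reference species)
ideal_species <- function() species("I0", 0, diameter = 1e-6, lam = 0)

# overlap-free starting positions on a simple cubic lattice
lattice_positions <- function(n, L) {
  m <- ceiling(n^(1 / 3))
  g <- (seq_len(m) - 0.5) * L / m
  as.matrix(expand.grid(g, g, g))[seq_len(n), , drop = FALSE]
}

# neutral box of +/- ions at random positions
random_ion_state <- function(n_pairs, L, lB, accuracy = 1e-3) {
  tab <- default_species_table()
  idx <- rep(c(match("Na+", tab$name), match("Cl-", tab$name)), n_pairs)
  pos <- matrix(stats::runif(3 * 2 * n_pairs, 0, L), 2 * n_pairs, 3)
  system_state(L, pos, idx, tab, lB = lB, ewald_accuracy = accuracy)
}

# 2x2x2 rocksalt lattice of +/- unit charges, nearest-neighbour distance a
rocksalt_state <- function(a = 2, lB = 1, accuracy = 1e-5) {
  tab <- default_species_table()
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * a
  q <- (-1)^rowSums(grid / a)
  idx <- ifelse(q > 0, match("Na+", tab$name), match("Cl-", tab$name))
  system_state(2 * a, grid + a / 4, idx, tab, lB = lB,
               ewald_accuracy = accuracy)
}

# central-difference volume-perturbation pressure estimate on a frozen state
volume_perturbation_pressure <- function(state, h = 1e-5) {
  N <- nrow(state$positions)
  V <- state$L^3
  U_at <- function(s) {
    st <- state
    st$L <- state$L * s
    st$positions <- state$positions * s
    total_energy(st)$total
  }
  dU <- (U_at(1 + h) - U_at(1 - h)) / (V * ((1 + h)^3 - (1 - h)^3))
  N / V - dU
}

# total charge carried by the particles of a state
state_net_charge <- function(state) sum(state$species_table$z[state$species_idx])
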