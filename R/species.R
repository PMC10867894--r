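#' Define a particle species
#'
#' @param name species label.
#' @param z integer charge number.
#' @param diameter effective diameter in reduced length units (ions default
#'   to 1.0 = 0.355 nm, monomers to 1.2 = 0.426 nm).
#' @param lam hydrophobicity parameter of the pair potential, in \[0, 1\];
#'   0 is a purely repulsive (athermal-solvent) bead.
#' @param exchangeable can the species be created/destroyed by reaction
#'   moves? Polymer monomers are not exchangeable.
#' @param monomer does the species sit on a polymer backbone?
#' @return one-row data frame.
#' @export
species <- function(name, z, diameter = 1.0, lam = 0, exchangeable = TRUE,
                    monomer = FALSE) {
  stopifnot(diameter > 0, lam >= 0, lam <= 1, z == round(z))
  data.frame(name = name, z = as.integer(z), diameter = diameter, lam = lam,
             exchangeable = exchangeable, monomer = monomer,
             stringsAsFactors = FALSE)
}

#' Default species table
#'
#' Registry of the particle kinds used throughout: polyanion (`A-`) and
#' polycation (`C+`) monomeric units, water self-ions, NaCl, generic divalent
#' ions `M2+`/`X2-`, and the three ionization states of a diprotic acid
#' (referred to as succinic acid, `H2SuA`/`HSuA-`/`SuA2-`). All small solutes
#' have diameter 1 (0.355 nm) and `lam = 0`; monomers have diameter 1.2
#' (0.426 nm).
#'
#' @param sigma_mon monomer diameter in reduced units.
#' @param lam_mon monomer hydrophobicity.
#' @return data frame with one row per species; row order defines the
#'   integer species index used in [system_state()].
#' @export
default_species_table <- function(sigma_mon = 1.2, lam_mon = 0) {
  rbind(
    species("A-", -1, sigma_mon, lam_mon, exchangeable = FALSE, monomer = TRUE),
    species("C+", +1, sigma_mon, lam_mon, exchangeable = FALSE, monomer = TRUE),
    species("Na+", +1),
    species("Cl-", -1),
    species("H+", +1),
    species("OH-", -1),
    species("M2+", +2),
    species("X2-", -2),
    species("H2SuA", 0),
    species("HSuA-", -1),
    species("SuA2-", -2)
  )
}

#' Harmonic bond parameters
#'
#' Defaults are the bead-spring values `K` = 827 kBT/nm^2 and rest length
#' `R0` = 0.426 nm, converted to reduced units.
#'
#' @param k_bond spring constant, kBT per squared reduced length.
#' @param r0 rest length, reduced.
#' @param us unit system used for the defaults.
#' @export
bond_params <- function(k_bond = spring_to_reduced(827, us),
                        r0 = nm_to_reduced(0.426, us), us = unit_system()) {
  stopifnot(k_bond > 0, r0 > 0)
  list(k_bond = k_bond, r0 = r0)
}

#' Build the per-pair interaction table
#'
#' Effective diameters follow the Lorentz-Berthelot arithmetic mean; the pair
#' hydrophobicity is the geometric mean of the per-species values (so any
#' pair involving a `lam = 0` bead is purely repulsive). Pairs involving a
#' monomer are cut off at `cutoff_factor` times the effective diameter
#' (2.5 sigma_mon = 1.065 nm for monomer-monomer at the defaults); pairs of
#' small solutes, which carry no attractive tail, are cut at the potential
#' minimum \eqn{2^{1/6}\sigma}. Each entry carries the shift constant that
#' makes the truncated potential exactly zero at its cutoff.
#'
#' @param species_table data frame from [default_species_table()].
#' @param cutoff_factor multiple of the effective diameter used as cutoff
#'   for pairs involving a monomer.
#' @return list of matrices `sigma`, `lam`, `rcut`, `ushift` (species x
#'   species, symmetric).
#' @export
pair_table <- function(species_table, cutoff_factor = 2.5) {
  n <- nrow(species_table)
  sg <- outer(species_table$diameter, species_table$diameter, function(a, b) (a + b) / 2)
  lm <- outer(species_table$lam, species_table$lam, function(a, b) sqrt(a * b))
  mono <- outer(species_table$monomer, species_table$monomer, `|`)
  rc <- ifelse(mono, cutoff_factor * sg, 2^(1 / 6) * sg)
  ush <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ush[i, j] <- .wca_unshifted(rc[i, j], sg[i, j], lm[i, j])
  }
  dimnames(sg) <- dimnames(lm) <- dimnames(rc) <- dimnames(ush) <-
    list(species_table$name, species_table$name)
  list(sigma = sg, lam = lm, rcut = rc, ushift = ush)
}

# unshifted lambda-WCA value (used for the shift constant)
.wca_unshifted <- function(r, sigma, lam) {
  s6 <- (sigma / r)^6
  core <- 4 * (s6^2 - s6) + (1 - lam)
  tail <- lam * 4 * (s6^2 - s6)
  ifelse(r < 2^(1 / 6) * sigma, core, tail)
}
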