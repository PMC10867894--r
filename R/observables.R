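#' Spherically averaged static structure factor
#'
#' \eqn{S(k) = \langle |\sum_j e^{i k \cdot r_j}|^2 \rangle / N} over the
#' selected species, evaluated on the discrete wavevectors of the periodic
#' box (\eqn{k = 2\pi n / L}) and averaged over spherical shells of width
#' \eqn{2\pi/L} starting at the smallest nonzero mode. The first bin is the
#' "k close to 0" bin used by the demixing criterion.
#'
#' @param trajectory a `pec_trajectory` (or a list with `frames`, `L`,
#'   `species_idx`, `species_table`).
#' @param species_names species included in the sum (e.g. `"A-"` for the
#'   monomer-monomer curve).
#' @param nmax largest integer mode per axis.
#' @return data frame with columns `k` (shell centre) and `S`.
#' @export
structure_factor <- function(trajectory, species_names, nmax = 6) {
  sel <- which(trajectory$species_table$name[trajectory$species_idx] %in%
                 species_names)
  if (!length(sel)) stop("empty species selection")
  if (!length(trajectory$frames)) stop("trajectory has no frames")
  raw <- cpp_structure_factor(trajectory$frames, as.integer(sel - 1L),
                              trajectory$L, as.integer(nmax))
  dk <- 2 * pi / trajectory$L
  shell <- pmax(1L, as.integer(round(raw$k / dk)))
  keep <- shell <= nmax
  S <- tapply(raw$S[keep], shell[keep], mean)
  data.frame(k = as.numeric(names(S)) * dk, S = as.numeric(S))
}

#' Chain conformation and relaxation metrics
#'
#' Time-averaged radius of gyration and end-to-end distance, the mean
#' squared displacement (MSD) of chain centres of mass, and a relaxation
#' time estimated as the lag at which the MSD first crosses \eqn{R_g^2}. A
#' warning is emitted when the trajectory is shorter than 10 relaxation
#' times. Frames must be unwrapped (trajectories from [run_langevin()]
#' are).
#'
#' @param trajectory a `pec_trajectory` with chain topology.
#' @return list with `Rg`, `end_to_end`, `msd` (data frame lag-time vs
#'   MSD), `relaxation_time` (NA when not crossed), `long_enough`.
#' @export
chain_metrics <- function(trajectory) {
  topo <- trajectory$topology
  if (!length(topo)) stop("trajectory has no chains")
  frames <- trajectory$frames
  nf <- length(frames)
  rg2 <- e2e <- numeric(0)
  coms <- array(0, c(nf, length(topo), 3))
  for (f in seq_len(nf)) {
    p <- frames[[f]]
    for (c in seq_along(topo)) {
      ch <- p[topo[[c]], , drop = FALSE]
      com <- colMeans(ch)
      coms[f, c, ] <- com
      rg2 <- c(rg2, mean(rowSums(sweep(ch, 2, com)^2)))
      e2e <- c(e2e, sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2)))
    }
  }
  lags <- seq_len(max(1, nf - 1))
  msd <- vapply(lags, function(l) {
    d <- coms[seq_len(nf - l) + l, , , drop = FALSE] -
      coms[seq_len(nf - l), , , drop = FALSE]
    mean(apply(d, c(1, 2), function(v) sum(v^2)))
  }, numeric(1))
  dtf <- if (nf > 1) diff(trajectory$times[1:2]) else 0
  lag_t <- lags * dtf
  Rg <- sqrt(mean(rg2))
  cross <- which(msd >= mean(rg2))
  tau <- if (length(cross)) lag_t[cross[1]] else NA_real_
  total_t <- if (nf) trajectory$times[nf] - trajectory$times[1] else 0
  long_enough <- is.finite(tau) && total_t >= 10 * tau
  if (!long_enough)
    warning("run shorter than 10 estimated relaxation times; ",
            "treat averages with caution")
  list(Rg = Rg, end_to_end = mean(e2e),
       msd = data.frame(lag = lag_t, msd = msd),
       relaxation_time = tau, long_enough = long_enough)
}

#' Ideal diprotic speciation (Henderson-Hasselbalch)
#'
#' Closed-form ideal fractions of the three protonation states of a
#' diprotic acid. The singly ionized fraction peaks at
#' pH = (pKa1 + pKa2)/2.
#'
#' @param pH pH value(s).
#' @param pKa1,pKa2 acidity constants.
#' @return for scalar `pH` a named vector (`H2SuA`, `HSuA-`, `SuA2-`);
#'   for vector `pH` a data frame with a `pH` column.
#' @export
ideal_speciation <- function(pH, pKa1 = 4.2, pKa2 = 5.6) {
  one <- function(p) {
    # Boltzmann-style enumeration over the three states, log space
    lw <- c(0, (p - pKa1) * log(10), (2 * p - pKa1 - pKa2) * log(10))
    w <- exp(lw - max(lw))
    stats::setNames(w / sum(w), c("H2SuA", "HSuA-", "SuA2-"))
  }
  if (length(pH) == 1) return(one(pH))
  out <- t(vapply(pH, one, numeric(3)))
  data.frame(pH = pH, out, check.names = FALSE)
}

#' Augmented Henderson-Hasselbalch ionization degree
#'
#' Ideal ionization corrected by the Boltzmann factor of the mean
#' electrostatic potential \eqn{\psi} felt by the ionized form of charge
#' \eqn{z}: \eqn{\alpha = [1 + 10^{pK_A - pH} e^{z\psi}]^{-1}} with
#' \eqn{\psi} in units of \eqn{k_B T / e}. \eqn{\psi = 0} recovers the
#' ideal curve; a potential shift of \eqn{\ln(10)/z} displaces the curve by
#' exactly one pH unit.
#'
#' @param pH pH value(s).
#' @param pKa acidity constant.
#' @param z charge number of the ionized form.
#' @param psi mean electrostatic potential, kBT/e.
#' @return degree of ionization in \[0, 1\].
#' @export
augmented_hh <- function(pH, pKa, z = -1, psi = 0) {
  1 / (1 + 10^(pKa - pH) * exp(z * psi))
}

#' Titration curve container
#'
#' Assembles measured per-state fractions over a pH grid together with the
#' ideal reference and the apparent pK shifts.
#'
#' @param pH pH grid.
#' @param fractions matrix/data frame (length(pH) x 3) of measured state
#'   fractions, columns `H2SuA`, `HSuA-`, `SuA2-`.
#' @param errors optional matrix of standard errors, same shape.
#' @param pKa1,pKa2 acidity constants of the ideal reference.
#' @return object of class `titration_curve` with `pH`, `fractions`,
#'   `errors`, `ideal`, `shifts`.
#' @export
titration_curve <- function(pH, fractions, errors = NULL, pKa1 = 4.2,
                            pKa2 = 5.6) {
  fractions <- as.matrix(fractions)
  stopifnot(nrow(fractions) == length(pH), ncol(fractions) == 3)
  ideal <- as.matrix(ideal_speciation(pH, pKa1, pKa2)[, -1])
  shifts <- vapply(1:3, function(j)
    apparent_pk_shift(pH, fractions[, j], j - 1, pKa1, pKa2), numeric(1))
  names(shifts) <- colnames(ideal)
  structure(list(pH = pH, fractions = fractions, errors = errors,
                 ideal = ideal, pKa1 = pKa1, pKa2 = pKa2, shifts = shifts),
            class = "titration_curve")
}

#' Apparent pK shift of one protonation state
#'
#' Horizontal offset (in pH units) that minimizes the squared deviation
#' between a measured state-fraction curve and the ideal reference curve of
#' that state; negative values mean the measured curve is displaced toward
#' lower pH, as electrostatic stabilization of the ionized forms predicts.
#'
#' @param pH sampled pH grid.
#' @param fraction measured fraction of the state at each pH.
#' @param n_ionized which state: 0 (neutral), 1 (singly ionized) or 2
#'   (doubly ionized).
#' @param pKa1,pKa2 acidity constants of the ideal reference.
#' @param window search half-width in pH units.
#' @return shift in pH units (measured = ideal shifted by this amount).
#' @export
apparent_pk_shift <- function(pH, fraction, n_ionized, pKa1 = 4.2,
                              pKa2 = 5.6, window = 3) {
  stopifnot(n_ionized %in% 0:2, length(fraction) == length(pH))
  obj <- function(s) {
    ref <- ideal_speciation(pH - s, pKa1, pKa2)[, n_ionized + 2]
    sum((fraction - ref)^2)
  }
  opt <- stats::optimize(obj, c(-window, window))
  if (min(abs(opt$minimum - c(-window, window))) < 1e-3)
    warning("apparent pK shift hit the search window edge; ",
            "crossover may lie outside the sampled pH range")
  opt$minimum
}

#' Debye-Hueckel prediction of the pK shift
#'
#' Limiting-law activity coefficient \eqn{\ln\gamma_z = -z^2 l_B \kappa /
#' [2(1+\kappa\sigma)]} (extended form when an ion size \eqn{\sigma} is
#' given) converted to the pK shift of the ionization step that forms the
#' z-valent state from the (z-1)-valent one:
#' \eqn{\Delta pK_z = (\ln\gamma_z + \ln\gamma_{H^+} - \ln\gamma_{z-1}) /
#' \ln 10}. The shift is negative (toward lower pH) and grows with the
#' valency of the state formed.
#'
#' @param z valency magnitude of the state formed (1 for the first
#'   deprotonation, 2 for the second, 0 returns 0).
#' @param ionic_strength reduced number-density ionic strength
#'   \eqn{I = \tfrac12 \sum c_i z_i^2}.
#' @param lB Bjerrum length, reduced units.
#' @param sigma ion diameter for the extended law (0 = limiting law).
#' @return predicted pK shift in pH units.
#' @export
dh_activity_shift <- function(z, ionic_strength, lB, sigma = 0) {
  stopifnot(ionic_strength > 0, lB > 0, z >= 0)
  if (z == 0) return(0)
  kappa <- sqrt(8 * pi * lB * ionic_strength)
  lng <- function(zz) -zz^2 * lB * kappa / (2 * (1 + kappa * sigma))
  (lng(z) + lng(1) - lng(z - 1)) / log(10)
}
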