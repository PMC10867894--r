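#' Pair potential energies
#'
#' `wca_energy()` evaluates the hydrophobicity-tunable WCA potential in its
#' truncated-and-shifted form: the repulsive core
#' \eqn{4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6] + (1-\lambda)\epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, the attractive tail
#' \eqn{\lambda \cdot 4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]} up to the
#' cutoff, and a constant shift making the potential exactly zero at and
#' beyond the cutoff. \eqn{\lambda = 0} gives the purely repulsive WCA
#' (athermal solvent); \eqn{\lambda = 1} restores the full Lennard-Jones
#' attraction depth.
#'
#' @param r distance(s), reduced units, > 0.
#' @param sigma effective pair diameter.
#' @param lam hydrophobicity in \[0, 1\].
#' @param rcut cutoff distance (defaults to the potential minimum, i.e. a
#'   purely repulsive interaction).
#' @return energy in kBT.
#' @export
wca_energy <- function(r, sigma = 1, lam = 0, rcut = 2^(1 / 6) * sigma) {
  if (any(r <= 0)) stop("wca_energy: distance must be positive")
  ush <- .wca_unshifted(rcut, sigma, lam)
  ifelse(r >= rcut, 0, .wca_unshifted(r, sigma, lam) - ush)
}

#' @rdname wca_energy
#' @param params bond parameters from [bond_params()].
#' @export
bond_energy <- function(r, params = bond_params()) {
  if (any(r < 0)) stop("bond_energy: distance must be non-negative")
  0.5 * params$k_bond * (r - params$r0)^2
}

#' @rdname wca_energy
#' @param z1,z2 integer charge numbers.
#' @param lB Bjerrum length, reduced units.
#' @export
coulomb_energy <- function(r, z1, z2, lB) {
  if (any(r == 0)) stop("coulomb_energy: singularity at r = 0")
  z1 * z2 * lB / r
}

#' Second virial coefficient of the pair potential
#'
#' \eqn{B_2 = -2\pi \int_0^\infty (e^{-\beta U(r)} - 1)\, r^2\, dr} by
#' adaptive quadrature over the truncated-shifted pair potential, splitting
#' the integral at the core/tail matching point for robustness. This maps
#' the hydrophobicity \eqn{\lambda} onto a solvent-quality scale:
#' \eqn{\lambda = 0} gives a positive, nearly hard-sphere value
#' (\eqn{2\pi\sigma^3/3}) and \eqn{B_2} decreases monotonically as
#' \eqn{\lambda} grows toward the theta point.
#'
#' @param lam hydrophobicity in \[0, 1\].
#' @param sigma pair diameter, reduced.
#' @param rcut cutoff of the truncated-shifted potential.
#' @param rel_tol quadrature relative tolerance.
#' @return \eqn{B_2} in reduced volume units.
#' @export
b2_from_lambda <- function(lam, sigma = 1.2, rcut = 2.5 * sigma,
                           rel_tol = 1e-10) {
  stopifnot(lam >= 0, lam <= 1)
  integrand <- function(r) (exp(-wca_energy(r, sigma, lam, rcut)) - 1) * r^2
  rmin <- 2^(1 / 6) * sigma
  lo <- tryCatch(
    stats::integrate(integrand, 0, rmin, rel.tol = rel_tol,
                     abs.tol = rel_tol, subdivisions = 500L),
    error = function(e) stop("b2_from_lambda: quadrature failed: ",
                             conditionMessage(e))
  )
  hi <- tryCatch(
    stats::integrate(integrand, rmin, rcut, rel.tol = rel_tol,
                     abs.tol = rel_tol, subdivisions = 500L),
    error = function(e) stop("b2_from_lambda: quadrature failed: ",
                             conditionMessage(e))
  )
  -2 * pi * (lo$value + hi$value)
}
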