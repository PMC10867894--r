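#' @useDynLib pecsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# physical constants (SI)
.const <- list(
  e = 1.602176634e-19,    # elementary charge, C
  eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
  kB = 1.380649e-23,      # Boltzmann constant, J/K
  NAv = 6.02214076e23     # Avogadro constant, 1/mol
)

#' Reduced unit system
#'
#' The simulation works in reduced units: the unit of length is the effective
#' ion diameter (default 0.355 nm), the unit of energy is \eqn{k_B T}
#' (temperature fixed at 298.15 K for all SI conversions), and the reference
#' concentration is \eqn{c^\circ = 1} mol/L. Particle mass is 1; it has no
#' effect on thermodynamic observables.
#'
#' @param length_nm nanometres per reduced length unit.
#' @param temperature temperature in kelvin used for SI conversions.
#' @return object of class `unit_system`.
#' @export
unit_system <- function(length_nm = 0.355, temperature = 298.15) {
  stopifnot(length_nm > 0, temperature > 0)
  structure(list(length_nm = length_nm, temperature = temperature,
                 reference_concentration = 1), class = "unit_system")
}

#' Convert lengths between nanometres and reduced units
#' @param x numeric lengths.
#' @param us a [unit_system()].
#' @return converted numeric vector.
#' @export
nm_to_reduced <- function(x, us = unit_system()) x / us$length_nm

#' @rdname nm_to_reduced
#' @export
reduced_to_nm <- function(x, us = unit_system()) x * us$length_nm

#' Convert concentrations between mol/L and reduced number density
#'
#' 1 mol/L corresponds to \eqn{N_A/10^{24}} particles per cubic nanometre,
#' i.e. about 0.0269 particles per cubic reduced length at the default
#' length unit.
#'
#' @inheritParams nm_to_reduced
#' @export
molar_to_reduced <- function(x, us = unit_system()) {
  x * .const$NAv * 1e-24 * us$length_nm^3
}

#' @rdname molar_to_reduced
#' @export
reduced_to_molar <- function(x, us = unit_system()) {
  x / (.const$NAv * 1e-24 * us$length_nm^3)
}

#' Convert a harmonic spring constant from kBT/nm^2 to reduced units
#' @param k spring constant in \eqn{k_B T}/nm\eqn{^2}.
#' @inheritParams nm_to_reduced
#' @export
spring_to_reduced <- function(k, us = unit_system()) k * us$length_nm^2

#' Bjerrum length from the relative permittivity
#'
#' \eqn{l_B = e^2 / (4 \pi \varepsilon_0 \varepsilon_r k_B T)}; the distance
#' at which two unit charges interact with energy \eqn{k_B T}. The default
#' permittivities in this package are 62 for the PEC phase (\eqn{l_B \approx
#' 0.9} nm) and 78 for the supernatant (\eqn{l_B \approx 0.72} nm).
#'
#' @param eps_r relative permittivity (dimensionless, > 0).
#' @param temperature kelvin.
#' @return Bjerrum length in nanometres.
#' @export
bjerrum_from_permittivity <- function(eps_r, temperature = 298.15) {
  stopifnot(all(eps_r > 0), temperature > 0)
  with(.const, e^2 / (4 * pi * eps0 * eps_r * kB * temperature)) * 1e9
}

#' @rdname bjerrum_from_permittivity
#' @param lB_nm Bjerrum length in nanometres.
#' @export
permittivity_from_bjerrum <- function(lB_nm, temperature = 298.15) {
  stopifnot(all(lB_nm > 0), temperature > 0)
  with(.const, e^2 / (4 * pi * eps0 * lB_nm * 1e-9 * kB * temperature))
}

#' Born estimate of the ion-transfer factor between phases
#'
#' Continuum-dielectric estimate of the solvation contribution to the
#' chemical potential of moving one ion of radius `r0` and valency `z` from
#' the supernatant (Bjerrum length `lB_sup`) into the PEC (`lB_pec`):
#' \eqn{\beta\mu^S = z^2 (l_B^{pec} - l_B^{sup}) / (2 r_0)}. Returns the
#' multiplicative factor \eqn{\exp(\beta\mu^S)} on a per-ion partition
#' coefficient. The two-phase sampler deliberately omits this contribution;
#' the factor is provided for post-hoc error estimates only.
#'
#' @param z integer charge number.
#' @param r0 ion radius (same length unit as the Bjerrum lengths).
#' @param lB_pec,lB_sup Bjerrum lengths of the two phases.
#' @return dimensionless factor, 1 for neutral species.
#' @export
born_transfer_factor <- function(z, r0, lB_pec, lB_sup) {
  stopifnot(r0 > 0)
  exp(z^2 * (lB_pec - lB_sup) / (2 * r0))
}
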