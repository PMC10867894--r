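---
title: "Modelling polyelectrolyte-complex coexistence and solute partitioning with pecsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polyelectrolyte-complex coexistence and solute partitioning with pecsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecsim)
```

## The physical problem

Mixing oppositely charged polyelectrolytes often produces two coexisting
liquid phases: a dense, polymer-rich polyelectrolyte complex (PEC, a complex
coacervate when liquid) and a dilute, essentially polymer-free supernatant.
Small ions, multivalent ions and weak acids distribute themselves between
the two phases; the partition coefficient of species $i$,

$$K_i = \frac{c_i^{\mathrm{pec}}}{c_i^{\mathrm{sup}}},$$

is set by the balance of steric repulsion, electrostatic correlations and —
for weak acids and bases — charge regulation. `pecsim` simulates both bulk
phases as separate periodic boxes that never exchange polymer but share one
set of reaction equilibrium constants, so that every exchangeable species
has equal chemical potential in both phases, and locates coexistence by
matching osmotic pressures.

## The microscopic model

All particles are spheres in implicit solvent, in reduced units: the ion
diameter $\sigma = 0.355$ nm is the length unit, $k_BT$ ($T = 298.15$ K)
the energy unit and $c^\circ = 1$ mol/L the reference concentration. Mass
is set to 1; it affects no thermodynamic observable.

Three interactions act between particles:

1. **Short range.** A hydrophobicity-tunable WCA form: the repulsive core
   $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + (1-\lambda)\epsilon$ below
   $2^{1/6}\sigma$, the tail $\lambda\,4\epsilon[(\sigma/r)^{12} -
   (\sigma/r)^6]$ above it, truncated and shifted to zero at the cutoff.
   $\lambda = 0$ (the default) is an athermal, purely repulsive solvent;
   growing $\lambda$ switches on attraction. `b2_from_lambda()` maps
   $\lambda$ to the second virial coefficient $B_2 = -2\pi\int
   (e^{-\beta U} - 1) r^2 \mathrm{d}r$ by adaptive quadrature, which is the
   solvent-quality scale used when the parameter is varied. Pair diameters
   follow the Lorentz–Berthelot mean; the pair $\lambda$ is the geometric
   mean. Pairs involving a monomer are cut at $2.5\,\sigma_{ij}$
   (monomer–monomer: $2.5 \times 0.426\ \mathrm{nm} = 1.065$ nm); pure
   small-solute pairs carry no tail and are cut at the potential minimum,
   which is the same physics at lower cost.
2. **Bonds.** Harmonic springs $\tfrac12 K (r - R_0)^2$ with $K = 827\,
   k_BT/\mathrm{nm}^2$ and $R_0 = \sigma_{\mathrm{mon}} = 0.426$ nm.
   Bonded neighbours also keep their nonbonded pair term (the common
   engine default). This choice is validated a posteriori: with it, the
   sampled bond-length distribution has mean $\approx 0.457$ nm and
   standard deviation $\approx 0.024$ nm, matching the model's published
   spread of 0.025 nm, whereas excluding the bonded pair term widens the
   spread to $\approx 0.034$ nm. A flag (`exclude_bonded_wca`) exposes the
   other convention.
3. **Electrostatics.** $u_{ij} = z_i z_j l_B / r$ with a per-phase Bjerrum
   length: $l_B = 0.90$ nm in the PEC ($\varepsilon_r \approx 62$) and
   $0.72$ nm in the supernatant ($\varepsilon_r \approx 78$). Periodic
   sums use classic Ewald summation with conducting (tinfoil) boundary,
   auto-tuned to a relative accuracy of $10^{-3}$ by default. The
   difference in solvation free energy implied by the two permittivities
   is deliberately not added to the exchange moves; `born_transfer_factor()`
   provides the continuum (Born) estimate of the resulting bias,
   $\exp[z^2(l_B^{\mathrm{pec}} - l_B^{\mathrm{sup}})/2r_0] \approx 1.7$
   per monovalent ion, for post-hoc error assessment.

## Sampling

**Dynamics.** Positions evolve by Langevin dynamics at $k_BT = 1$ using
the BAOAB splitting with $\delta t = 0.01\tau$ and friction $\gamma = 1$ by
default. With $\gamma = 0$ and no noise the integrator reduces to velocity
Verlet, which the test-suite uses to verify second-order energy
conservation. All randomness is drawn from R's RNG, so a seed makes whole
runs replayable, reaction moves included.

**Reaction moves.** Composition fluctuates through grand-reaction Monte
Carlo: insertion/deletion of neutral ion combinations (NaCl, HCl, NaOH,
H$^+$+OH$^-$, MCl$_2$), in-box acid dissociations, and neutral
solute-exchange combinations for each ionization state of the diprotic
acid (pK$_{A,1}$ = 4.2, pK$_{A,2}$ = 5.6, the values for succinic acid). A
move picks a reaction uniformly, a direction uniformly, converts particles
in place where the stoichiometry allows, inserts the remainder uniformly
in the box (velocities Maxwell-distributed) and accepts with

$$\min\left[1,\ \Gamma^{\xi} \prod_i \frac{N_i^0!}{(N_i^0 + \xi\nu_i)!}
(V c^\circ)^{\xi\nu_i}\, e^{-\beta\Delta E}\right],$$

evaluated in log space. Only neutral stoichiometries are accepted at
construction time, so electroneutrality is conserved exactly, move by
move. Polymer beads are not exchangeable; touching them is a hard error.

**Reservoir mapping.** `constants_from_reservoir()` converts targets (pH,
NaCl concentration, total acid, divalent salt) into the constant set
$\Gamma$ at the ideal-gas level by mass action. Of the four ion-pair
constants only two are independent: the water ionic product is fixed
($10^{-14}$) and reservoir electroneutrality fixes the fourth, so
$\Gamma_{\mathrm{NaCl}}\Gamma_w = \Gamma_{\mathrm{HCl}}\Gamma_{\mathrm{NaOH}}$
holds by construction, and the composed solute-exchange constants close
all thermodynamic cycles over the network (both identities are asserted in
the tests). The salt target is interpreted as the added NaCl, with the pH
adjusted by implicit NaOH or HCl — this is why, with interactions on, the
*realised* composition must be measured from an auxiliary reservoir
simulation (`calibrate_reservoir()`); the measured values are generally
not round numbers, and at low ionic strength they sit slightly above the
ideal targets because Debye–Hückel activity lowering favours insertions.
pH is reported on the concentration scale, $-\log_{10} c_{H^+}$, matching
the bookkeeping of the reaction moves.

**Cadence.** The production pattern interleaves dynamics and chemistry;
the published cadence is 500 reaction attempts every $10^4$ steps, and
both numbers are arguments of `run_phase()`.

## Locating coexistence

A PEC box is prepared by `build_initial_pec()`: fully extended rods on a
regular lattice, relaxed, then compressed by $\Delta L = 0.7\sigma$ per
step (with relaxation runs between) until the monomer volume fraction
$\phi_{\mathrm{mon}} = N_{\mathrm{mon}}(\pi/6)\sigma_{\mathrm{mon}}^3 / V$
reaches its target. For each candidate $\phi$ the osmotic pressure
difference to the supernatant, $\Delta P(\phi)$, is measured with the
virial estimator (ideal + short-range + bonded + Ewald contributions; the
reciprocal-space virial is the analytic volume derivative of the truncated
sum, cross-checked in the tests against a central-difference volume
perturbation). The branch with $\Delta P \gtrsim 0$ — operationally,
points with $\Delta P > -2\,\mathrm{stderr}$, since the negative branch is
prone to in-box demixing — is fitted with the phenomenological monotone
form

$$\Delta P(\phi) = a_0 + a_1 / \tan(\phi - a_2),$$

by weighted nonlinear least squares (inverse-variance weights by default;
the weighting convention is configurable because it is not dictated by the
method) and the coexistence composition $\phi^0$ is the bracketed root of
the fitted curve inside the sampled $\phi$ range. Its uncertainty comes
from parametric resampling of the fit covariance. Self-consistency is then
screened with the monomer–monomer structure factor: the box is flagged as
demixing when the smallest-$k$ shell of $S(k)$ is the global maximum, and
a flagged point at $\phi^0$ invalidates the coexistence result. Tie-line
concentrations of every exchangeable species in the two phases give the
partition coefficients, with $K > 1$ meaning accumulation in the PEC.
`partition_from_masses()` implements the gravimetric estimator used for
bench experiments, under the documented default that the hydrated complex
has approximately the density of water.

## Analysis layer

* `structure_factor()` — $S(k)$ on the discrete box modes, spherically
  binned in shells of $2\pi/L$; verified against an $O(N^2)$ double loop.
* `chain_metrics()` — $R_g$, end-to-end distance, MSD of chain centres of
  mass and a relaxation-time estimate (lag at which the MSD crosses
  $R_g^2$), warning when the run is shorter than ten relaxation times.
* `ideal_speciation()`, `augmented_hh()` — the ideal diprotic reference
  curves and the mean-field ionization $\alpha = [1 + 10^{pK_A - pH}
  e^{z\psi}]^{-1}$.
* `apparent_pk_shift()` — the horizontal offset between measured and ideal
  state-fraction curves, measured on state populations (not on the overall
  ionization degree) because populations are what the two-phase runs
  report per state.
* `dh_activity_shift()` — the Debye–Hückel prediction for the pK shift of
  the step forming the $z$-valent state; both the limiting and extended
  law are exposed, and only limit behaviour and signs are asserted, since
  the theory is not quantitative at coacervate ionic strengths.

Errors on all composition observables are block-averaged (5 blocks by
default) to respect the MC/MD autocorrelation.

## Numerical choices

* Ewald parameters are tuned from the standard truncation-error estimates
  with a 10% safety margin; the two-charge probe, an 8-charge direct image
  sum (converted to tinfoil boundary by removing the surface-dipole term)
  and the rocksalt Madelung constant pin the achieved accuracy in the
  tests.
* Short-range pairs use all-pairs minimum-image evaluation rather than
  cell lists. At the box sizes this package targets interactively (tens to
  a few thousand particles) the $O(N^2)$ kernel in C++ is faster than the
  bookkeeping it would replace; the correctness burden cell lists would
  carry (skin management, rebuild triggers) disappears with them.
* The reaction moves recompute the total energy of the trial state rather
  than maintaining incremental structure-factor updates; at the same box
  sizes this is simple and fast enough, and it is exact by construction.
* Insertions are plain uniform trial positions — no cavity biasing and no
  continuous-fractional coupling — so acceptance degrades in very dense
  boxes; this bounds the polymer volume fractions the sampler handles
  well, not the method's formal validity.
* `nlsLM` (Levenberg–Marquardt) fits the pressure curve, with $a_2$
  bounded to keep $\tan(\phi - a_2)$ on a single branch; starting values
  come from a linear solve at a heuristic $a_2$.

## What the synthetic generators emulate

The package is exercised end-to-end on generated inputs only:

* *chains/PEC boxes* (`build_single_chain()`, `build_initial_pec()`) —
  the real preparation pipeline at reduced size;
* *ideal reservoirs* — boxes whose exact composition is known from mass
  action, giving parameter-free oracles for the reaction sampler;
* *synthetic pressure curves* — generated from known $(a_0, a_1, a_2)$
  with stated Gaussian noise and seed, so the fitter's recovery can be
  checked against ground truth;
* *constructed $S(k)$ shapes* — flat, small-$k$ divergent, and
  mid-$k$-peaked curves for the demixing classifier.

These fixtures reproduce the *mechanisms* of real data (thermal noise,
finite counts, discrete $k$-grids) but not its slow collective dynamics:
desk-scale boxes (8 chains of 8 beads, $10^3$–$10^4$-step cycles) have
far shorter relaxation times and far larger composition fluctuations than
production systems (64 chains of 32 beads, $10^7$ steps). Passing tests
therefore demonstrate correctness of the machinery and the *direction* of
the physical effects — divalent accumulation ($K > 1$), slight monovalent
exclusion at elevated salt ($K \lesssim 1$), acid partitioning rising with
pH — not converged production values. The published production numbers
(e.g. divalent $K \approx 6$–9, acid $K_{\mathrm{tot}} \approx 5$ at high
pH, a 0.3-pH shift of the divalent population) require cluster-scale runs
at full system size.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script choose sizes a laptop handles
comfortably: the bond-length benchmark runs a single 32-bead chain for
$2\times10^5$ equilibration plus $0.6$–$1\times10^6$ production steps;
two-phase trend checks use 8-chain PEC boxes with 40 cycles of 150 steps
and ~90 reaction attempts; ideal-reservoir oracles use boxes of 10–30
particles with $10^4$–$10^5$ attempts. These are the package's default
demonstration sizes, chosen so that every claim it makes is recomputed
from scratch at install time; all are arguments, not constants.

## Known limitations

* No polymer in the supernatant: valid far from the critical point only;
  the demixing flag is the self-consistency guard, and no critical-point
  or spinodal machinery is provided.
* Fixed polymer charges: charge regulation applies to the small solutes,
  not the backbone; pH-dependent polymer ionization is out of scope.
* Symmetric polyanion/polycation content means zero Donnan potential and
  equal pH in both phases; asymmetric mixing ratios are not modelled.
* Implicit solvent: water content is defined volumetrically
  ($\phi_{\mathrm{water}} = 1 - \phi_{\mathrm{mon}} - \phi_{\mathrm{ion}}$),
  comparable to gravimetric mass fractions only up to a density factor.
* No barostat: pressure matching happens across fixed-volume runs, which
  is what the coexistence protocol requires.
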