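# pecsim

Coarse-grained simulation of polyelectrolyte complex (PEC) coexistence and
solute partitioning in R.

Mixing oppositely charged polyelectrolytes produces a dense polymer-rich
phase (the PEC, a complex coacervate when liquid) coexisting with a dilute,
essentially polymer-free supernatant. `pecsim` answers the question this
two-phase equilibrium poses for small solutes: given a supernatant of known
pH and salt content, what is the composition of the coexisting PEC, and how
do ions, multivalent ions and weak acids partition between the phases,

&nbsp;&nbsp;&nbsp;&nbsp;*K_i = c_i^pec / c_i^sup* ?

It is written for soft-matter and physical-chemistry researchers who want a
desk-scale, fully scriptable implementation of the two-box approach:

* **Model** — bead–spring polymers and spherical solutes in implicit
  solvent: a hydrophobicity-tunable WCA pair potential (truncated–shifted,
  with the λ ↔ B₂ mapping by quadrature), harmonic bonds
  (K = 827 k_BT/nm², R₀ = 0.426 nm) and Coulomb interactions with a
  per-phase Bjerrum length (0.90 nm in the PEC, ε_r ≈ 62; 0.72 nm in the
  supernatant, ε_r ≈ 78) under tinfoil Ewald summation.
* **Sampling** — BAOAB Langevin dynamics (dt = 0.01 τ, k_BT = 1)
  interleaved with grand-reaction Monte Carlo: neutral insertion/deletion
  combinations for NaCl/HCl/NaOH/water self-ions and divalent salt, acid
  dissociation of a diprotic solute (pK_A 4.2 / 5.6), and composed
  solute-exchange reactions, accepted with the reaction-ensemble
  probability min[1, Γ^ξ Π N!/(N+ξν)! (Vc⊖)^{ξν} e^{−βΔE}].
* **Coexistence** — the pressure–composition protocol: a series of PEC
  boxes across monomer volume fractions φ, the fit
  ΔP(φ) = a₀ + a₁/tan(φ − a₂) to the ΔP ≳ 0 branch, root-finding for φ⁰
  with ΔP(φ⁰) = 0, and a structure-factor demixing flag (smallest-k shell
  being the global maximum of S(k)) as the self-consistency screen.
* **Analysis** — tie lines and partition coefficients, titration curves
  with ideal Henderson–Hasselbalch references and apparent-pK shifts,
  Debye–Hückel shift predictions, S(k), chain metrics and MSD-based
  relaxation diagnostics.

## Worked example: who goes where?

A small two-phase experiment — a supernatant at pH 7 with 150 mM NaCl and
20 mM divalent salt (MCl₂), coupled to an 8-chain PEC box at monomer
volume fraction 13%:

```r
library(pecsim)
set.seed(42)

tab <- default_species_table()
cons <- constants_from_reservoir(pH = 7, c_salt = 0.15, c_divalent = 0.02)

lB_pec <- nm_to_reduced(bjerrum_from_permittivity(62))  # 2.55 sigma
lB_sup <- nm_to_reduced(bjerrum_from_permittivity(78))  # 2.02 sigma

pec <- build_initial_pec(4, 8, target_phi = 0.13, species_table = tab,
                         lB = lB_pec, relax_steps = 300)
pr  <- run_phase(pec, cons$reactions, n_cycles = 40, md_steps = 150,
                 mc_attempts = 90)

sup <- build_reservoir_box(11, cons$ideal_concentrations, lB = lB_sup,
                           species_table = tab)
sr  <- run_phase(sup, cons$reactions, n_cycles = 40, md_steps = 150,
                 mc_attempts = 90)

tie_line(pr, sr)
```

```
  species      c_sup     c_pec        K  K_stderr
1     Cl- 0.31458876 0.4530898 1.440261 0.2235713
2     M2+ 0.07320071 0.1718617 2.347814 0.4699138
3     Na+ 0.16818734 0.1093665 0.650266 0.1633012
```

Reading the table: the divalent ion accumulates in the complex (K ≈ 2.3 ≫ 1,
dragging extra Cl⁻ with it for neutrality), while Na⁺ mildly prefers the
supernatant (K < 1) — the qualitative fingerprint of coacervate ion
partitioning. At this desk scale the error bars are large; production-size
boxes (32+32 chains of 32 beads, 10⁷-step runs) sharpen the same trends
into quantitative coefficients.

To locate a coexistence composition from a pressure scan, fit the ΔP(φ)
table and read off φ⁰:

```r
fit <- fit_dp_curve(read_tsv("dp_curve.tsv"))
fit$phi0        # volume fraction with Delta P = 0
fit$valid       # FALSE if the nearest point is demixed or no root exists
```

A thin command-line front-end (`inst/cli/pecsim.R`) exposes the same
pipeline as subcommands `run`, `titrate`, `scan`, `coexist`, `analyze`
and `fixtures`; every invocation writes a manifest (config hash, seed,
versions) next to its outputs.

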