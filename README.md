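# scqedhf — strong-coupling QED Hartree–Fock in R

Molecules placed in optical cavities couple to the quantized electromagnetic
field strongly enough to form polaritons — hybrid light–matter states that
can change ground-state chemistry. Describing this from first principles
requires treating electrons and the cavity photon on the same footing.
`scqedhf` implements **strong-coupling QED Hartree–Fock (SC-QED-HF)**, a
mean-field theory for a molecule coupled to one effective cavity mode, whose
molecular orbitals remain well defined (origin invariant, intermolecularly
consistent) at arbitrary coupling — together with the second-order
self-consistent-field algorithms that make it converge reliably.

The package is aimed at method developers and computational chemists who
want a transparent, fully self-contained implementation at desk scale: it
ships its own Gaussian integral engine (McMurchie–Davidson, s/p/d shells),
embedded benchmark geometries and basis sets, and an exact-diagonalization
oracle used to validate every physics claim in the test suite.

## The model

The light–matter system is described by the Pauli–Fierz Hamiltonian in the
length gauge and dipole approximation (atomic units, one cavity mode of
frequency ω, coupling λ, polarization ε):

    H = H_el + ω b†b + sqrt(ω/2) λ (d·ε)(b + b†) + (λ²/2)(d·ε)²

with `d` the molecular dipole operator. The SC-QED-HF ansatz applies an
orbital-specific coherent-state transformation to a closed-shell
determinant and the photon vacuum,

    |ψ⟩ = exp(κ) U_SC |HF⟩ ⊗ |0⟩,
    U_SC = exp( -(λ/sqrt(2ω)) Σ_p η_p Ẽ_pp (b† - b) ),

where the `Ẽ_pp` are number operators in the *dipole basis* (the orbital
basis diagonalizing `d·ε`) and the η_p are per-orbital photon displacement
amplitudes. All photon expectation values are analytic: the electronic
integrals are simply dressed by Gaussian factors
`exp(-λ²(η_p-η_q)²/4ω)` (one-electron) and
`exp(-λ²(η_p-η_q+η_r-η_s)²/4ω)` (two-electron), plus dipole self-energy
terms, so the energy is an ordinary restricted-HF functional with
η-dependent effective integrals. As λ → ∞ the optimal η_p approach the
dipole eigenvalues and the ansatz becomes exact.

The two parameter classes — orbital rotations κ and coherent-state
parameters η — condition very differently: the η subspace is soft
(curvature ∝ λ²) and strongly coupled, which makes naive gradient updates
stagnate. The package provides three drivers:

* **`gb-diis`** — Roothaan–Hall + DIIS for the density, damped
  steepest-descent + DIIS for η (the historical baseline; documented to
  plateau),
* **`tr-nr`** — trust-region Newton–Raphson on the concatenated (κ, η)
  vector using matrix-free κκ and ηη Hessian linear transformations and a
  level-shifted preconditioned conjugate-gradient micro-solver,
* **`gb-dbi`** — Roothaan–Hall + DIIS for the density with a Newton step
  for η from direct inversion of the dense η–η Hessian block (no
  micro-iterations).

## Worked example

```r
library(scqedhf)

mol <- fixture_molecule("h2o", basis = "sto-3g")   # embedded geometry
cav <- cavity(lambda = 0.01, omega_ev = 2.71, polarization = c(0, 0, 1))
fit <- scqed_hf(mol, cav, algorithm = "tr-nr")
summary(fit)
```

```
SC-QED-HF summary (tr-nr)
  total energy        -74.962870830387 hartree
  field-free RHF      -74.962928246434 hartree
  cavity shift          0.000057416048 hartree
  converged         TRUE after 5 macro-iterations
  mean micro-iterations per solve  3.25
  final max|E^(1)|  3.34353e-12
  final ||g_k||/N_k 5.03099e-13   ||g_eta||/N_eta 8.70504e-13
```

The cavity shift is the energy the molecule pays for being dressed by the
vacuum field (dipole self-energy minus the relaxation the η parameters and
orbitals buy back); `coef(fit)` returns the converged η_p, and `plot(fit)`
draws the per-iteration convergence diagnostics. A YAML-driven command-line
interface with the same functionality lives at `inst/cli/polariton-scf`
(`polariton-scf run CONFIG`, `validate`, `selftest`).

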