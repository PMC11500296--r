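---
title: "SC-QED-HF: model, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SC-QED-HF: model, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the physics it implements,
the algorithmic decisions behind the three SCF drivers, and the numerical
choices (tolerances, initialization, degenerate cases) a user or reviewer
would want spelled out. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The model

A molecule in an optical cavity exchanging energy with one effective photon
mode is described by the length-gauge, dipole-approximation Pauli-Fierz
Hamiltonian

$$ H = H_{el} + \omega\, b^\dagger b
   + \sqrt{\tfrac{\omega}{2}}\,\lambda\,(d\cdot\epsilon)(b + b^\dagger)
   + \tfrac{\lambda^2}{2} (d\cdot\epsilon)^2 , $$

where $d$ is the total (electronic + nuclear) molecular dipole operator,
$\epsilon$ a real unit polarization vector, $\lambda$ the coupling strength
in atomic units and $\omega$ the cavity frequency. The dipole self-energy
term makes $H$ bounded from below.

All electronic quantities are expressed in the *dipole basis*: the
orthonormal orbital basis diagonalizing the projected electronic dipole
$(d^e\cdot\epsilon)$, with eigenvalues $\tilde d_{pp}$ sorted ascending.
Slater determinants in this basis become exact eigenstates at infinite
coupling, which is what makes it the natural reference frame for strong
coupling.

The SC-QED-HF ansatz dresses each dipole-basis orbital with its own photonic
coherent state,

$$ |\psi\rangle = e^{\kappa}\, U_{SC}\, |HF\rangle\otimes|0\rangle,
   \qquad
   U_{SC} = \exp\Big( -\tfrac{\lambda}{\sqrt{2\omega}}
     \sum_p \eta_p \tilde E_{pp} (b^\dagger - b) \Big), $$

with occupied-virtual rotation generators $\kappa_{ai}$ and per-orbital
displacement amplitudes $\eta_p$. Taking the vacuum average analytically
(no photonic Hilbert space is ever represented in the mean-field code)
gives a closed-shell energy functional in which

* one-electron integrals are scaled by
  $\exp[-\lambda^2(\eta_p-\eta_q)^2/4\omega]$,
* two-electron integrals by
  $\exp[-\lambda^2(\eta_p-\eta_q+\eta_r-\eta_s)^2/4\omega]$,
* and the residual displacement mismatch contributes
  $\tfrac{\lambda^2}{2}\big\langle (d\cdot\epsilon-\sum_p\eta_p\tilde
  E_{pp})^2 \big\rangle$, which expands into effective one- and
  two-electron integrals diagonal in the dipole basis (including the
  nuclear-dipole cross terms).

Both Gaussian factors reduce to 1 at $\lambda=0$ or for uniform $\eta$, are
bounded in $(0,1]$, and retain the permutational symmetries implied by
their difference arguments; the tests verify all of this numerically, and
every derivative expression in the package is checked against central
finite differences — the package treats the finite-difference oracle, not
the derivation, as the source of truth.

Two structural consequences are worth noting. First, because the dipole
basis diagonalizes a fixed AO-space operator, it does not depend on the
current orbitals: the package computes it once per system and represents
the orbital state as an orthogonal matrix $W$ over that basis. Rebuilding
the basis after each orbital update — the presentation one would use if the
MO basis were primary — is mathematically identical, and the fixed-basis
form makes the $\eta$-to-orbital association automatic (ties in the dipole
spectrum cannot reshuffle $\eta$ between iterations). Second, with the
effective integrals in hand, SC-QED-HF is formally ordinary restricted HF
with $\eta$-dependent integrals: the Fock matrix, gradients and Hessian
blocks are all gradient-style contractions of dressed quantities, which is
what keeps the method at mean-field cost.

For charged systems a rigid translation $a$ shifts the dipole operator by
$a\cdot\epsilon\, Q_{tot}$; a uniform shift of all $\eta_p$ absorbs it
exactly, so the variational optimum is origin invariant. The test suite
demonstrates both the invariance of the relaxed theory on NH$_4^+$ and its
violation (by roughly 0.1 hartree over a 10-bohr translation) when $\eta$
is frozen at zero, the ablation that mimics an undressed QED-HF treatment.

## Parameters that matter

* `lambda` (a.u.): light-matter coupling; 0.005-0.01 spans the strong-
  coupling regimes studied at desk scale. At 0 every quantity reduces to
  RHF (tested to 1e-9 hartree).
* `omega` (hartree; accepted as eV and converted by 1/27.211386): cavity
  frequency. Enters only through $\lambda^2/4\omega$ and the bilinear term.
* `polarization`: real unit vector; rejected if its norm deviates from 1 by
  more than 1e-12 rather than silently renormalized.
* `energy_threshold`, `gradient_threshold` (default 1e-10 a.u.): a state is
  converged when both the energy change and the absolute maximum of the
  concatenated gradient fall below threshold; the per-class scaled norms
  $\|g_\kappa\|_2/N_\kappa$ and $\|g_\eta\|_2/N_\eta$ are reported each
  iteration.
* `eta_step` (gb-DIIS only, default 0.1): damped steepest-descent step for
  $\eta$. The baseline's stagnation behaviour depends on it — smaller steps
  stagnate more slowly but later; it is a knob precisely because no value
  makes the baseline robust.

## The three drivers

**gb-DIIS (baseline).** Roothaan-Hall diagonalization of the dipole-basis
Fock matrix with Pulay DIIS on the density (commutator error vector), and
damped steepest descent plus a second DIIS buffer for $\eta$. The $\eta$
subspace has curvature of order $\lambda^2$ with strongly coupled,
near-singular directions, so no diagonal information is available to scale
the gradient step: on several fixtures the scaled $\eta$-gradient norm
flatlines orders of magnitude above threshold while the orbital class
converges — reproduced by the test suite on ammonia/6-31G.

**tr-NR.** One joint Newton step per macro-iteration on the concatenated
$(\kappa, \eta)$ vector, with the level-shifted system
$(E^{(2)}-\mu I)\,\Delta z = -E^{(1)}$ solved matrix-free by preconditioned
conjugate gradients. By default only the $\kappa\kappa$ and $\eta\eta$
blocks are applied; the mixed blocks are implemented (and
finite-difference-verified) but disabled, because they cost an extra
$N^4$ contraction per product while saving almost no iterations — the two
parameter classes are nearly decoupled, and enabling them reaches the same
stationary point (tested to 1e-9 hartree). $\Delta\kappa$ is applied
through the exact exponential map, $\Delta\eta$ additively; steps are
accepted or rejected by the trust-region gain ratio.

**gb-DBI.** Roothaan-Hall + DIIS for the density, and for $\eta$ a direct
Newton step $\eta \leftarrow \eta - H_{\eta\eta}^{-1} g_\eta$ using the
dense $\eta\eta$ block (built by partial traces of the already-dressed
integrals at $N^4$ cost, inverted at $N^3$). No micro-iterations. The
inverse is taken through an eigenvalue-floored pseudo-inverse (floor 1e-8)
because the block is legitimately near-singular — weakly occupied dipole
orbitals barely couple to the field; if the block is not positive definite
(possible far from convergence) the driver falls back to a damped gradient
step for that iteration.

## Trust-region specifics

The trust-region constants are the package's own choices, made for the
curvature structure of this problem rather than inherited from generic
defaults: initial radius 2.0, expansion x2 after a successful
boundary-limited step, shrinkage x0.7 when the gain ratio drops below 0.25,
rejection on negative gain. The $\eta$ directions are soft (curvature
$\propto \lambda^2$), so natural Newton steps have norms of order 1-10 in
dipole units; a small radius with timid expansion forces many
boundary-limited macro-iterations without improving robustness. When the
predicted quadratic reduction falls below the floating-point noise floor of
the total energy (1e-13 x |E|), the gain ratio is numerically meaningless
and the (tiny) step is accepted unconditionally — without this rule the
final iterations toward a 1e-10 gradient threshold can reject forever.

The micro-solver is preconditioned by the Fock-difference diagonal
$4(F_{aa}-F_{ii})$ (floored at 1e-3) for the $\kappa$ block — the
diagonally dominant part of the orbital Hessian — and by the dense
$\eta\eta$ block itself (Cholesky, ridge 1e-7 relative) for the $\eta$
part, which is built each macro-iteration anyway for the diagnostics. The
boundary value of the shift is located by the one-point model update
$\sigma \leftarrow \sigma\,\|x(\sigma)\|/(0.9\,\Delta)$ — exact when soft
modes dominate, safeguarded by bisection — warm-started from the previous
macro-iteration at $\sigma_{prev}/8$, and each CG run aborts as soon as its
iterate leaves the trust region. Micro-iteration counts reported are the
total CG iterations over all solves of a macro-iteration. The per-solve
residual tolerance is $\min(10^{-2}\|g\|, 10^{-6})$ (inexact-Newton
forcing), capped at 100 iterations per solve.

## Initialization, determinism, degenerate cases

* Orbitals start from a converged field-free RHF; $\eta_p$ start at the
  dipole eigenvalues $\tilde d_{pp}$ (the exact infinite-coupling values
  and the frozen-$\eta$ reference the field uses).
* Everything is deterministic: integrals, eigensolvers with ascending-order
  sorting and a largest-component-positive sign fix, DIIS, CG. Repeated
  runs agree to 1e-12 (tested); there is no randomness anywhere in the
  drivers.
* Degenerate dipole eigenvalues are handled by the deterministic secondary
  ordering of the symmetric eigensolver plus the sign fix; because the
  dipole basis is computed once per system, no between-iteration
  reassociation of $\eta$ can occur by construction.
* Systems beyond 200 basis functions abort with a clear message: the
  package holds full $N^4$ tensors in memory. Cholesky-vector batching of
  the two-electron integrals is the known extension hook for larger
  systems and is deliberately not implemented.
* Only closed-shell (even-electron, restricted) references are supported;
  odd electron counts are rejected at input.

## The integral backend and embedded data

AO integrals (overlap, kinetic, nuclear attraction, dipole moments,
two-electron repulsion) are computed by the package's own
McMurchie-Davidson engine (C++): Hermite expansion of Gaussian products,
Boys-function downward recursion, Cartesian-to-real-spherical
transformation for d shells. It is validated in the tests against
closed-form s-Gaussian formulas evaluated independently in R, and the
STO-3G data file is cross-checked against the Slater-zeta scaling rule that
defines that basis. Basis sets (STO-3G, 6-31G, cc-pVDZ, aug-cc-pVDZ for
H/C/N/O) are transcribed standard literature values stored as plain text.
Benchmark geometries (H2, H2O, NH3, CH2O, NH4+) are repository-standard
equilibrium structures; iteration-count benchmarks test the convergence
class of the algorithms, which is robust to small geometry differences.

## Validation oracles

Three independent oracles back the test suite:

1. **Finite differences** (`fd_gradient`): central differences of the
   public energy, step 1e-4, tolerance 1e-6 against every analytic
   gradient and Hessian-vector product at fixed recorded non-stationary
   states.
2. **Photon-Fock-space exact diagonalization**
   (`exact_polariton_ground_state`): the full Pauli-Fierz Hamiltonian
   assembled from Jordan-Wigner operator matrices in the (determinant) x
   (photon number) basis, for at most 4 spin orbitals, converged in the
   photon cutoff to 1e-10. At $\lambda = 0$ it reproduces an independently
   coded closed-form CI; at finite coupling it provides the variational
   lower reference that the mean-field energy must stay above (verified
   over five $(\lambda, \omega)$ settings).
3. **Plain RHF** (`rhf`): an AO-basis Roothaan-Hall + DIIS code kept
   separate from the dipole-basis machinery, used for the zero-coupling
   reduction checks and as the initial guess.

## What the tests do and do not show

The embedded systems are small closed-shell molecules in modest bases; the
test suite demonstrates correctness of every term and derivative of the
functional, the variational bound, origin invariance, cross-algorithm
agreement to 1e-9 hartree, and the convergence-class claims (second-order
drivers converge in a handful of macro-iterations at thresholds of 1e-10
where the gradient baseline plateaus). Problem sizes were chosen so the
full suite — including one aug-cc-pVDZ benchmark with about 64 spherical
basis functions — completes in a few minutes. What passing tests do *not*
show: behaviour for open-shell systems, multi-mode or chiral cavities,
response properties, or systems large enough to need integral batching —
all outside this package's scope.
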