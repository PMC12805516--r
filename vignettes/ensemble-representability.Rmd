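---
title: "Methods: variational ensemble N-representability testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variational ensemble N-representability testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensrep)
```

This vignette records the algorithmic and design decisions behind `ensrep`,
in the package's own terms. The aim is that a reader can re-derive every
number the package produces from what is written here.

## 1. Problem statement

Let Γ be a candidate p-body reduced density matrix (p-RDM) for N electrons in
M spin-orbitals, normalized to trace p!·C(N, p). Γ is **pure-state
N-representable** if Γ = Γ_p(ψ) for some N-electron state |ψ⟩, and **ensemble
N-representable** if Γ = Σ_k w_k Γ_p(ψ_k) for a mixed state. The package
decides both by minimizing the squared Hilbert–Schmidt distance

D(θ) = ‖Γ_p(ψ(θ)) − Γ‖²_F

over a growing, adaptively selected unitary ansatz ψ(θ). D = 0 at a feasible
point certifies representability; a converged D > 0 lower-bounds the distance
to the representable set and the evolved Γ_p is returned as the nearest
representable matrix found.

## 2. Purification: the ensemble test as a pure test

A mixed state of an M-spin-orbital system is the partial trace of a pure
state on system ⊗ bath with a bath of the same size. `initial_state("ensemble",
...)` therefore builds the sector with N electrons in the system register and
N in a mirrored bath register, starting from the product determinant
|ref⟩_sys ⊗ |ref⟩_bath. The operator pool acts on *all* 2M spin-orbitals
(entangling the registers), while `compute_rdm` traces out the bath by
indexing only system annihilators. Reachability: any ensemble decomposition
Σ w_k |ψ_k⟩⟨ψ_k| lifts to the pure state Σ √w_k |ψ_k⟩|k⟩ provided the bath
sector holds enough orthogonal tags — with C(M, N) bath determinants this is
never binding for the targets considered. Consequently the ensemble search
converges to exact zero precisely on the ensemble-representable set.

Two initial-state conventions are used: `"pure"` is the reference determinant
in the system-only sector; `"ensemble"` is the product purification. Both are
unentangled starting points with the *same* system 1-RDM.

## 3. The pool and the closed-form exponential

Generators are the antihermitian (here: real antisymmetric) excitation
differences

* singles: O = a_i†a_k − a_k†a_i,
* doubles: O = a_i†a_j†a_k a_l − a_l†a_k†a_j a_i,

built as sparse matrices in the occupation-word basis with Jordan–Wigner sign
bookkeeping. Each generator is T − Tᵀ with T a *signed partial permutation*
(at most one ±1 per row and column), which forces O³ = −O. Hence the rotation
truncates exactly:

exp(θO) = I + sin(θ)·O + (1 − cos(θ))·O².

No Trotterization and no series truncation is involved anywhere; every state
in the ansatz is produced by exact orthogonal maps (verified against dense
`Matrix::expm` in the test suite).

**Symmetry toggles.** The pool always conserves the electron number of each
register separately (bath-number conservation is what makes the purification
argument work). Conservation of total or per-register S_z is available via
`pool_config(conserve_sz = ...)` but is **off by default**, for two reasons
recorded during development: (i) the canonical thermal ensembles mix all S_z
sectors, and their mirrored-bath purification is not reachable inside a fixed
total-S_z sector; (ii) for the (4e, 4o) equal-weight single-substitution
2-RDM target the pure-state minimum attained with the unrestricted pool
(D = 4.25) is strictly lower than the minimum over the S_z-restricted
orbit — the reference results are only reproduced without the restriction.
All bundled scenarios therefore use `conserve_sz = "none"`.

Pool sizes under the toggles are logged at scenario start (e.g. 406 operators
for the pure (4e, 8 spin-orbital) sector, 2828 for its purified double
register) and are informational, not load-bearing: the algorithm's fixed
points are determined by the reachable orbit, not the operator count.

## 4. RDMs, distance, and gradients

`compute_rdm(psi, p)` assembles Γ_p from images χ_k = a_k|ψ⟩ (p = 1) or
χ_{i<j} = a_j a_i|ψ⟩ (p = 2): Γ[(i), (k)] = ⟨χ_i, χ_k⟩, so Γ is positive
semidefinite by construction and the trace normalization p!·C(N, p) holds
identically. The 2-RDM is stored over all M² ordered pairs with explicit
antisymmetry (zero (i,i) rows); internally the i<j representative block is
used, with the distance scaled ×4 to account for the redundancy.

All states are stored as **real** vectors. Every pool generator is real
antisymmetric and every shipped target is real symmetric, so the reachable
orbit of the real reference determinant is real; complex targets are handled
by treating the imaginary part as a constant (unreachable) offset in D. This
halves memory and doubles speed at zero loss of generality for the problem
class.

Gradients are analytic. For the ansatz ψ = U_m(θ_m)···U_1(θ_1)ψ₀ with
U = exp(θO), ∂D/∂θ_m = 4·⟨w, O_m ψ_{(m)}⟩ where ψ_{(m)} is the state after
the first m rotations and w is the adjoint vector obtained by applying the
remaining rotations' transposes to the RDM-residual back-action. A single
forward + backward sweep yields all m derivatives; the test suite checks them
against central finite differences at interior points, including repeated
operators.

## 5. The growth loop

Each macro-iteration of `adapt_run`:

1. computes the exact distance gradient of every pool operator at θ_new = 0
   (a single residual back-action, then one sparse matvec per operator);
2. appends the operator with the largest |gradient|, initialized at 0;
3. re-optimizes **all** angles by BFGS with the analytic gradient
   (full re-optimization each iteration, not just the new angle);
4. stops when D ≤ `zero_threshold` (`exact_zero`), the largest pool gradient
   is below `delta` (`gradient_small`), `max_iter` is reached, or the
   improvement stalls.

**Saddle escape.** At a determinant initial state with a determinant-mixture
target, the residual operator is diagonal in the number basis, so *every*
pool generator has exactly zero first-order gradient although D is far from
its minimum — gradient selection alone would terminate at the starting point.
Whenever max|g| < `delta` but D > `zero_threshold`, the engine performs a
deterministic second-order step: a 1-D line search of D along each candidate
operator, appending the best single-operator improvement at its 1-D-optimal
angle, followed by full re-optimization. This is a deliberate deviation from
initializing every new angle at zero; it is deterministic (no randomness) and
is only triggered at first-order stationary points.

`classify_rdm` runs the pure and ensemble searches and reports
`"pure"` (both zero), `"ensemble_only"` (only ensemble zero), or
`"not_representable"` (neither), together with the evolved nearest
representable RDM from the ensemble run.

## 6. Thermal and noisy targets

`hydrogen_chain_integrals(n, spacing)` evaluates STO-3G integrals for linear
H_n chains with the package's own s-orbital Gaussian module (overlap,
kinetic, nuclear attraction, ERI via the Boys function); H₂ molecular
orbitals are symmetry-determined (identical to RHF for a homonuclear 2-AO
dimer), H₃ uses the core-Hamiltonian eigenbasis. The values are validated in
the tests against standard published H₂ integrals and the H₂ FCI energy.
`thermal_rdm` diagonalizes the Hamiltonian on the full N-electron sector
(all S_z blocks) and forms the canonical-ensemble p-RDM at temperature kT,
defaulting to the first spectral gap. `add_noise(rdm, eps, seed)` adds a
symmetric Gaussian perturbation of scale eps with a seeded, state-preserving
RNG so that noisy scenarios are reproducible seed by seed.

## 7. The spectral audit

Beyond Coleman's ensemble conditions (0 ≤ λ ≤ 1, Σλ = N for p = 1), the
package ships the complete list of linear inequalities on the *ordered*
natural-occupation spectrum λ₁ ≥ … ≥ λ₈ that characterize pure-state
1-RDMs for N = 4 electrons in 8 spin-orbitals: the ordinary Pauli bound
λ₁ ≤ 1 plus 14 generalized Pauli (Klyachko) constraints, stored as integer
coefficient rows in `inst/extdata/klyachko_4_8.txt`.

The table was re-derived numerically rather than copied: the sorted-spectrum
polytope's support function h(c) = max over pure states of c·λ↓(ψ) was
maximized over the 4-electron sector of an 8-spin-orbital space (alternating
eigenvector iteration plus quasi-Newton polishing on the Stiefel-lifted
objective), candidate facets were detected as integer directions whose
support falls strictly below the Pauli-only linear-programming bound, bounds
were rationalized to small integers, redundant rows were eliminated by exact
linear programming, and the final system was certified two-sidedly: (a) no
sampled pure state (random, sparse, and structured families) violates any
inequality, and (b) every vertex of the candidate polytope is attained by an
explicitly constructed pure state (distance ≤ 1e-9), so the listed system is
neither too tight nor too loose. The same pipeline run on the known
(N = 3, d = 7) case reproduces its four classical facets exactly, which was
used as the method's validation gate.

`klyachko_check(rdm_or_spectrum)` sorts the spectrum, pads with zeros if the
RDM lives in fewer than 8 spin-orbitals, and reports each inequality's
slack and the satisfied count; `coleman_check` covers the ensemble
conditions for both p = 1 and p = 2.

## 8. Scenarios, determinism, and the reference surface

A scenario is a YAML document with `system` (electron count, orbitals,
reference), `target` (mixture, thermal, or file; optional noise block),
`algorithms`, `settings`, and `pool` sections, validated with field-path
error messages before anything runs. `run_scenario` writes a result JSON, a
per-iteration trace CSV per algorithm, the evolved RDM, and a spectral audit
JSON — with no timestamps and seeded RNG, so reruns are byte-identical.

`reference_tables()` holds the published reference values the tool
reproduces; `run_table`/`report_table` recompute every cell and compare:
exact cells to 1e-3, converged near-zero cells against their printed floor,
noisy cells by order of magnitude and median monotonicity across noise
strengths (5 seeds per strength, median over seeds). The acceptance script
(`scripts/acceptance.R`) recomputes the six scalar targets from scratch
against the installed package and never reads the reference tables.
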