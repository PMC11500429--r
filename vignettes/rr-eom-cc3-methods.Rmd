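---
title: "Rank-reduced EOM-CC3: model, numerics and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-reduced EOM-CC3: model, numerics and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrcc3)
```

## The model

Equation-of-motion coupled cluster describes an excited state as an
eigenvector of the similarity-transformed Hamiltonian
$\bar H = e^{-T} H_N e^{T}$ built on a ground-state coupled-cluster
reference: $[\bar H, R]\,|0\rangle = \omega R\,|0\rangle$, with $R = R_1 +
R_2 + R_3$ and the excitation energy $\omega$ obtained directly from the
commutator form.  In EOM-CC3 the singles and doubles projections are treated
as in EOM-CCSDT, while the triples equation keeps only the bare-Fock
coupling among triples.  With a canonical reference this makes the triples
explicit:
$$
R_{ijk}^{abc} \;=\;
\frac{\big[\hat P_3\,\gamma\big]_{ijk}^{abc}}
     {\omega - (\varepsilon_{abc}-\varepsilon_{ijk})},
$$
where $\hat P_3$ sums the six simultaneous permutations of the
(occupied, virtual) index pairs and, in the T1-dressed formulation used
throughout this package (dressed integrals $(pq|\tilde{\,}rs)$ absorb all
explicit $T_1$ terms), the generator for the excited state is
$$
\gamma_{ijk}^{abc} = \sum_d R_{ij}^{ad}\,(bd|\tilde{\,}ck)
                   - \sum_l R_{il}^{ab}\,(lj|\tilde{\,}ck)
\;+\; \Big[\text{same form with } T_2 \text{ and } (pq|rs)' \Big],
$$
with $(pq|rs)'$ the directional derivative of the dressing in the direction
of $R_1$ — the exact integral representation of the two-body part of
$[\tilde H, R_1]$, so that $\langle\mu_3|[[\tilde H,T_2],R_1]|0\rangle =
\langle\mu_3|[[\tilde H,R_1],T_2]|0\rangle$ needs no additional diagram
class.  The ground-state CC3 triples are the $\omega = 0$, $R_2 \to T_2$,
$R_1 \to 0$ special case of the same expression.  The triples feed back into
the singles and doubles residuals through fixed linear functionals
(`dense_sigma_triples()` and their factorized twins), and the ground-state
triples additionally couple to $R_1$ through the derivative-dressed
integrals (the $\langle\mu_2|[[\tilde H,T_3],R_1]|0\rangle$ term).

## The rank reduction

Both triples tensors are compressed in the Tucker-3 format with one shared
orthonormal factor per state,
$R_{ijk}^{abc} = r_{XYZ} V_{ia}^X V_{jb}^Y V_{kc}^Z$, of ranks `N_svd`
(ground) and `N_SVD` (excited) — the method's only accuracy parameters.
Because a pair-permuted tensor projected with a shared factor equals the
core with permuted rank indices, the $\hat P_3$ symmetrization acts directly
on $(X,Y,Z)$, and after rotating the projector so that the projected
one-body matrix $G_{XY} = \sum_{ia} V_{ia}^X(\varepsilon_a -
\varepsilon_i)V_{ia}^Y$ is diagonal (canonical values $\varepsilon_X$), the
compressed triples equation becomes an element-wise division by
$\omega - \varepsilon_X - \varepsilon_Y - \varepsilon_Z$.  A guard (default
$10^{-6}$ hartree) aborts with the offending $(X,Y,Z)$ when a denominator
approaches zero — the compressed analogue of an intruder state.

The projectors are fixed **before** the CC3/EOM-CC3 iterations.  They are
computed by higher-order orthogonal iteration on perturbative guess
amplitudes: the (T)-type first-order triples of the converged CCSD doubles
for the ground state, and the analogous tensor with $R_2^{\rm CCSD}$ and an
$\omega^{\rm CCSD}$-shifted denominator for the excited state.  Each HOOI
sweep needs only the partial projection $R_{ia,YZ}$ of the guess tensor,
evaluated with Laplace-separated denominators so the rank-6 tensor is never
formed; the update takes the leading left singular vectors of its unfolding.
The factorized core tensor is then recomputed with the current Ritz value
$\omega$ in every sigma build, so the folded triples stay
$\omega$-self-consistent while the subspace stays frozen.

## Parameters that matter

* `n_svd`, `n_SVD` — triple-excitation subspace sizes, as absolute integers
  or multiples of the active molecular-orbital count (`"1.4*nmo"`).  Default
  policy: the diagonal `N_SVD = N_svd = 1.0*N_MO`, the recommended setting
  for triple-zeta-like problems; `1.4*N_MO` is the suggested value for
  double-zeta-like ones.  At `O*V` the method is exact (asserted in tests).
* Ground-state convergence `1e-8` (energy) / `1e-7` (residual) — tighter
  than the Davidson thresholds so amplitude noise cannot pollute excitation
  energies; Davidson thresholds `1e-5` hartree / `1e-4` maximum residual
  amplitude (the delivered-state contract, asserted in the acceptance
  tests).
* Laplace tolerance `1e-6` relative — the quadrature is built by a
  trapezoidal rule on a log-transformed integration variable, with the point
  count grown adaptively until a dense scan of the requested denominator
  range meets the tolerance; points and weights are strictly positive, and
  the range actually used by a run is re-asserted at provider construction.
* Cholesky threshold `1e-8` — the density-fitting error is then far below
  the method error.  The metric route uses the symmetric inverse square
  root $V^{-1/2}$ (either metric convention reproduces the same fitted
  integrals).
* HOOI: at most 50 sweeps, stop when the captured variance changes by less
  than `1e-4` relative; stacked-SVD damping engages when a sweep would
  decrease the captured variance, the signature of the two-state oscillation
  seen for excited-state amplitudes.
* Triples-denominator guard `1e-6` hartree, batching and memory limits are
  irrelevant at the package's verification scale but the contraction engine
  enforces the allocation contract (below) regardless.

## Design choices where the design was open

* **Representation.**  The CCSD and EOM-CCSD singles/doubles machinery is
  implemented in spin orbitals, where the antisymmetrized working equations
  are standard and independently checkable against full CI; every
  triples-specific quantity lives in the spatial-orbital pair representation
  that the Tucker compression requires (only there does the pair-permutation
  identity hold, and only there is the factorization free of
  six-unique-index steps).  The two representations meet in the
  singlet fold: spatial contributions are expanded to spin-orbital arrays by
  the exact singlet relations.  The triples→singles/doubles contraction
  tables used by both the dense oracle and the factorized path were derived
  by symbolic spin summation of the standard spin-orbital matrix elements
  through the exact spatial-to-spin amplitude map, and verified to machine
  precision against determinant-space commutators.
* **HOOI initialization.**  A pilot basis from the SVD of the doubles pair
  matrix (completed with a seeded random orthonormal basis when the doubles
  rank is too small).  An identity pilot would require the full
  $(OV)^3$ unfolding, which the allocation contract forbids; the doubles
  pilot is physically motivated — the guess triples are doubles-driven — and
  HOOI converges in a handful of sweeps from it.
* **Guess amplitudes.**  (T)-type doubles-driven first-order triples (the
  `[T]` alternative differs only in the singles-driven terms, which the
  guess does not need).
* **Excited-state HOOI start.**  Cold start from the guess-state doubles
  pilot by default; `warm_start = TRUE` reuses the ground projector.
* **Davidson.**  Non-Hermitian, right eigenvectors only, oblique
  Rayleigh–Ritz, restart on subspace saturation, root homing by overlap.
  Complex pairs in the search space are tolerated unless they crowd out the
  requested lowest real roots.  The EOM-CC3 stage is a single-root
  $\omega$-outer loop around the same machinery.
* **`%R2`.**  Defined on the singles+doubles part of the eigenvector under
  unit normalization, counting each unique excitation once, so
  `%R1 + %R2 = 100` exactly.

## Numerical contracts

* No tensor with six occupied/virtual indices is ever materialized on the
  rank-reduced path; every factorized contraction runs through a network
  contractor that executes one GEMM per step and refuses intermediates
  beyond order five.
* The compressed core is exactly permutation-symmetric; projectors are
  orthonormal to `1e-10`; canonicalization preserves the span exactly.
* Degenerate canonical values are ordered ascending with a deterministic
  sign convention (largest-magnitude component positive).

## What the synthetic fixtures do and do not show

The generator builds closed-shell MO Hamiltonians with exactly
8-fold-symmetric, positive-semidefinite two-electron tensors and an exactly
canonical Fock matrix with a prescribed HOMO–LUMO gap; interaction strength
0.10–0.15 keeps CCSD comfortably convergent.  These fixtures exercise every
equation of the method at desk scale — exactness limits against full CI,
full-rank equivalence between the rank-reduced and dense paths, rank-scan
convergence — with problem sizes O ≤ 3, V ≤ 5 (rank-6 oracles up to
O·V = 40).  They do not emulate real molecular integral structure: no shell
structure, no near-linear dependence in the fitting basis, weak static
correlation, and triples contributions of a few times $10^{-4}$ hartree.
Consequently the tests demonstrate correctness of the equations and the
advertised limits of the approximation, not chemical accuracy claims for
real molecules, which additionally require a real integral backend
(FCIDUMP import is provided for that purpose).

## Known limitations

Closed-shell singlet right eigenstates only; no point-group symmetry; no
transition moments or $R_0$; dense in-memory tensors sized for verification
work, not production molecules; the dense oracle refuses O·V > 40.  States
dominated by double excitations converge more slowly with rank, mirroring
the method's behaviour; a near-zero shifted triples denominator raises an
intruder-state error instead of silently diverging.

## A compact demonstration

```{r demo, eval = FALSE}
fx <- fixture_hamiltonian("small")
res <- run_rr_eom_cc3(fx$ints, fx$spaces, state = 1)
c(omega_ev = res$omega_ev, ccsd_ev = res$omega_ccsd_ev,
  pct_r2 = res$percent_r2)
rank_scan(fx$ints, fx$spaces, grid = c(2L, 4L, 6L))
```
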