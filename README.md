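# rrcc3 — rank-reduced EOM-CC3 excitation energies

`rrcc3` computes singlet vertical excitation energies of closed-shell
molecules with the **rank-reduced equation-of-motion coupled-cluster method
with approximate triple excitations (RR-EOM-CC3)**, together with the dense
canonical EOM-CC3, EOM-CCSD, CCSD and full-CI reference machinery needed to
verify it at small system sizes.

## The method

Canonical EOM-CC3 scales as *N*⁷ because of the triply excited amplitudes
T³ and R³.  RR-EOM-CC3 compresses both in the Tucker-3 format over compound
occupied–virtual pairs,

    T_ijk^abc = t_xyz U_ia^x U_jb^y U_kc^z ,
    R_ijk^abc = r_XYZ V_ia^X V_jb^Y V_kc^Z ,

with one shared orthonormal factor matrix (*projector*) per state.  The
projectors span triple-excitation subspaces of user-chosen sizes `N_svd`
(ground state) and `N_SVD` (excited state) — the method's only accuracy
knobs; with the recommended diagonal policy `N_SVD = N_svd ≈ N_MO` the
compression error is several times below the inherent accuracy of canonical
EOM-CC3, and at `N_svd = N_SVD = O·V` the method is exact.

The projectors are found **before** the coupled-cluster iterations by
higher-order orthogonal iteration (HOOI) on perturbative guess amplitudes —
(T)-type amplitudes built from the CCSD doubles for the ground state, and
their excited-state analogue built from the EOM-CCSD doubles R₂ with the
energy denominator shifted by ω^CCSD.  The partial projections that drive
HOOI are evaluated at reduced cost through a numerical Laplace transform of
the inverse orbital-energy denominators; the full-rank amplitudes are never
formed.  Oscillating HOOI iterations are quenched by a stacked-SVD damping
step, and the converged projector is rotated so that the projected one-body
matrix is diagonal (canonical values ε_X), which reduces the compressed
triples equation to

    r_XYZ = [ P3 γ̂ ]_XYZ / (ω − ε_X − ε_Y − ε_Z) ,

where γ̂ is the projected triples generator built from T1-dressed,
density-fitted two-electron integrals.  All triples contributions to the
singles/doubles residuals are evaluated in factorized form — every step is a
GEMM over at most five indices; no rank-6 tensor is ever materialized.

## Worked example

The package ships three deterministic synthetic closed-shell Hamiltonians
(`tiny`, `small`, `medium`, also as FCIDUMP files under `inst/extdata/`).
The full pipeline — CCSD → ground HOOI → RR-CC3 → block-Davidson EOM-CCSD →
excited HOOI → single-root RR-EOM-CC3 — runs from R:

```r
library(rrcc3)
fx <- fixture_hamiltonian("small")      # O = 2, V = 3 closed-shell fixture
res <- run_rr_eom_cc3(fx$ints, fx$spaces, state = 1)
```

or from the shell through the thin wrapper:

```sh
Rscript inst/cli/rrcc3 rr-eom-cc3 --fixture small
```

which prints

```
stage              rr-eom-cc3
state              1
n_svd              5
n_SVD              5
omega_hartree      1.463237006
omega_ev           39.817
omega_ccsd_ev      39.831
percent_r2         0.7
```

`omega_hartree`/`omega_ev` is the RR-EOM-CC3 excitation energy of the first
singlet state at the default diagonal rank policy (`N_svd = N_SVD = N_MO`,
here 5 of a maximum O·V = 6); `omega_ccsd_ev` is the EOM-CCSD stage it
started from — the 0.014 eV difference is the approximate-triples
contribution — and `percent_r2` is the doubles character of the state (a
valence-like, singles-dominated state here; values near 100 flag doubly
excited states).  A rank scan shows the controlled convergence toward the
exact (full-rank) result:

```sh
Rscript inst/cli/rrcc3 rank-scan --fixture small --grid 2,4,6
```

```
 rank    omega omega_ev    abs_error
    2 1.463602 39.82664 0.0003831530
    4 1.463365 39.82018 0.0001457192
    6 1.463219 39.81622 0.0000000000
```

At `rank = 6 = O·V` the rank-reduced energy coincides with the dense
canonical EOM-CC3 oracle; the error decreases (with the mild oscillation
expected of the method) as the subspace grows.

## Scope and limitations

Real arithmetic, closed-shell references and singlet right eigenstates only;
no spatial point-group symmetry, left eigenvectors, transition moments or
triplet states.  Inputs are MO-basis Hamiltonians (FCIDUMP or the synthetic
generator); the package does not evaluate AO integrals.  The dense oracle
refuses systems with O·V > 40 by design.  See the methods vignette
(`vignettes/rr-eom-cc3-methods.Rmd`) for the working equations, parameter
choices and verification strategy.
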