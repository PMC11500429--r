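# Shared fixtures and slow intermediates, computed once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fix_tiny <- function() cached("tiny", fixture_hamiltonian("tiny"))
fix_small <- function() cached("small", fixture_hamiltonian("small"))
fix_medium <- function() cached("medium", fixture_hamiltonian("medium"))

ccsd_tiny <- function() cached("ccsd_tiny", {
  fx <- fix_tiny()
  solve_ccsd(spin_orbital_basis(fx$ints, fx$spaces),
             conv_energy = 1e-12, conv_residual = 1e-11)
})

ccsd_small <- function() cached("ccsd_small", {
  fx <- fix_small()
  solve_ccsd(spin_orbital_basis(fx$ints, fx$spaces),
             conv_energy = 1e-12, conv_residual = 1e-11)
})

# dressed quantities of the small fixture at its converged CCSD amplitudes
dressed_small <- function() cached("dressed_small", {
  fx <- fix_small()
  cc <- ccsd_small()
  df <- cholesky_factorize(fx$ints, tol = 1e-12)
  t1sp <- cc$t1[1:2, 1:3]
  dr <- dress_t1(df, fx$ints$h, t1sp, 2L)
  list(df = df, dr = dr, gt = dressed_eri(dr), t1sp = t1sp,
       t2sp = cc$t2[1:2, 2 + 1:2, 1:3, 3 + 1:3])
})

# ground CC3 solutions of the small fixture (dense and full-rank RR)
cc3_small <- function() cached("cc3_small", {
  fx <- fix_small()
  list(dense = solve_cc3_ground_dense(fx$ints, fx$spaces,
                                      conv_energy = 1e-11,
                                      conv_residual = 1e-10),
       rr = solve_cc3_ground_rr(fx$ints, fx$spaces, n_svd = 6L,
                                conv_energy = 1e-11, conv_residual = 1e-10))
})

eom_ccsd_small <- function() cached("eom_ccsd_small", {
  fx <- fix_small()
  solve_eom_ccsd(fx$ints, fx$spaces, ccsd_small(), n_roots = 1L,
                 conv_energy = 1e-9, conv_residual = 1e-6, max_iter = 100L)
})

# random P3-symmetric triples tensor
rand_w3 <- function(O, V, seed) {
  set.seed(seed)
  symmetrize_p3(array(stats::rnorm(O^3 * V^3), dim = c(O, O, O, V, V, V)))
}

# random pair-symmetric spatial doubles
rand_d2 <- function(O, V, seed) {
  set.seed(seed)
  x <- array(stats::rnorm((O * V)^2), dim = c(O, O, V, V))
  (x + aperm(x, c(2, 1, 4, 3))) / 2
}


# internal helpers used heavily by the tests
ein2 <- rrcc3:::ein2
tperm <- rrcc3:::tperm
amax <- rrcc3:::amax
fnorm <- rrcc3:::fnorm
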