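# EOM-CCSD: sigma vector, guesses, Davidson solver, diagnostics.

# dense singlet effective Hamiltonian by column probing (coordinates:
# spatial singles + pair-symmetric spatial doubles packed upper-triangular)
.probe_matrix <- function(env, O, V) {
  nov <- O * V
  pairs <- which(upper.tri(matrix(0, nov, nov), diag = TRUE), arr.ind = TRUE)
  dim_tot <- nov + nrow(pairs)
  unpack <- function(x) {
    c1 <- matrix(x[seq_len(nov)], O, V)
    Cm <- matrix(0, nov, nov)
    for (r in seq_len(nrow(pairs))) {
      Cm[pairs[r, 1], pairs[r, 2]] <- x[nov + r]
      Cm[pairs[r, 2], pairs[r, 1]] <- x[nov + r]
    }
    c2 <- aperm(array(Cm, dim = c(O, V, O, V)), c(1, 3, 2, 4))
    list(r1 = rrcc3:::singlet_r1_so(c1), r2 = rrcc3:::singlet_r2_so(c2))
  }
  pack <- function(s1, s2) {
    c1 <- s1[seq_len(O), seq_len(V), drop = FALSE]
    c2 <- s2[seq_len(O), O + seq_len(O), seq_len(V), V + seq_len(V),
             drop = FALSE]
    Cm <- matrix(aperm(c2, c(1, 3, 2, 4)), nov, nov)
    c(as.numeric(c1), Cm[upper.tri(Cm, diag = TRUE)])
  }
  A <- matrix(0, dim_tot, dim_tot)
  for (col in seq_len(dim_tot)) {
    x <- numeric(dim_tot); x[col] <- 1
    v <- unpack(x)
    sg <- sigma_eom_ccsd(env, v$r1, v$r2)
    A[, col] <- pack(sg$s1, sg$s2)
  }
  A
}

test_that("CIS guesses diagonalize the singles block and are orthonormal", {
  fx0 <- synth_hamiltonian(2, 3, seed = 17, interaction_scale = 0)
  cc0 <- solve_ccsd(spin_orbital_basis(fx0$ints, fx0$spaces))
  env0 <- eom_env(fx0$ints, fx0$spaces, cc0)
  gs <- cis_guess(env0, 3L)
  # Fock-only Hamiltonian: guess energies are orbital-energy differences
  gaps <- sort(as.numeric(outer(-fx0$spaces$eps_occ, fx0$spaces$eps_virt, "+")))
  expect_equal(vapply(gs, function(g) g$omega, numeric(1)), gaps[1:3],
               tolerance = 1e-10)
  for (i in 1:3) for (j in 1:3)
    expect_equal(rrcc3:::eom_dot(gs[[i]], gs[[j]]), as.numeric(i == j),
                 tolerance = 1e-10)
  expect_error(cis_guess(env0, 100L), "range")
})

test_that("the sigma vector is linear and vanishes on the zero vector", {
  fx <- fix_small()
  env <- eom_env(fx$ints, fx$spaces, ccsd_small())
  z1 <- matrix(0, env$no, env$nv)
  z2 <- array(0, dim = c(env$no, env$no, env$nv, env$nv))
  s0 <- sigma_eom_ccsd(env, z1, z2)
  expect_equal(amax(s0$s1), 0, tolerance = 1e-14)
  expect_equal(amax(s0$s2), 0, tolerance = 1e-14)
  set.seed(2)
  va <- list(r1 = rrcc3:::singlet_r1_so(matrix(rnorm(6), 2, 3)),
             r2 = rrcc3:::singlet_r2_so(rand_d2(2, 3, 21)))
  vb <- list(r1 = rrcc3:::singlet_r1_so(matrix(rnorm(6), 2, 3)),
             r2 = rrcc3:::singlet_r2_so(rand_d2(2, 3, 22)))
  sa <- sigma_eom_ccsd(env, va$r1, va$r2)
  sb <- sigma_eom_ccsd(env, vb$r1, vb$r2)
  sab <- sigma_eom_ccsd(env, 2 * va$r1 - 3 * vb$r1, 2 * va$r2 - 3 * vb$r2)
  expect_lt(amax(sab$s1 - (2 * sa$s1 - 3 * sb$s1)), 1e-11)
  expect_lt(amax(sab$s2 - (2 * sa$s2 - 3 * sb$s2)), 1e-11)
})

test_that("Davidson roots match the column-probed dense spectrum and, for a
           two-electron system, full CI", {
  fx <- fix_tiny()
  cc <- ccsd_tiny()
  env <- eom_env(fx$ints, fx$spaces, cc)
  A <- .probe_matrix(env, 1L, 2L)
  evals <- sort(Re(eigen(A)$values))
  roots <- solve_eom_ccsd(fx$ints, fx$spaces, cc, n_roots = 2L,
                          conv_energy = 1e-10, conv_residual = 1e-9,
                          max_iter = 120L)
  for (r in roots)
    expect_lt(min(abs(evals - r$omega)), 1e-8)
  # EOM-CCSD is exact for two electrons: compare with FCI excitations
  fci <- fci_reference(fx$ints)
  wfci <- fci$energies - fci$energies[1]
  for (r in roots)
    expect_lt(min(abs(wfci[-1] - r$omega)), 1e-8)
})

test_that("the block Davidson solver reproduces a dense nonsymmetric
           eigensolution", {
  set.seed(33)
  n <- 50
  A <- diag(seq(0.5, 6, length.out = n)) + 0.05 * matrix(rnorm(n * n), n)
  ev <- eigen(A)
  re <- sort(Re(ev$values[abs(Im(ev$values)) < 1e-10]))
  sigma_op <- function(v) list(s1 = A %*% v$r1, s2 = 0 * v$r2)
  env <- list(eo = diag(A), ev = 0)
  guesses <- lapply(1:4, function(k) {
    r1 <- matrix(0, n, 1); r1[order(diag(A))[k], 1] <- 1
    eom_vector(r1, array(0, dim = c(n, n, 1, 1)), omega = NA)
  })
  roots <- suppressWarnings(
    block_davidson(sigma_op, guesses, 3L, env,
                   conv_energy = 1e-10, conv_residual = 1e-8,
                   max_iter = 200L))
  for (k in 1:3)
    expect_lt(abs(roots[[k]]$omega - re[k]), 1e-8)
  # residual criterion holds at return
  for (r in roots) {
    s <- sigma_op(r)
    expect_lt(amax(s$s1 - r$omega * r$r1), 1e-7)
  }
})

test_that("the doubles-character diagnostic behaves as a percentage", {
  O <- 2L; V <- 3L
  r1 <- rrcc3:::singlet_r1_so(matrix(rnorm(6), O, V))
  z2 <- array(0, dim = c(2 * O, 2 * O, 2 * V, 2 * V))
  v1 <- eom_vector(r1 / sqrt(sum(r1^2)), z2)
  expect_equal(percent_r2(v1), 0, tolerance = 1e-12)
  r2 <- rrcc3:::singlet_r2_so(rand_d2(O, V, 5))
  nrm <- sqrt(0.25 * sum(r2^2))
  v2 <- eom_vector(matrix(0, 2 * O, 2 * V), r2 / nrm)
  expect_equal(percent_r2(v2), 100, tolerance = 1e-10)
  # %R1 + %R2 = 100 for any normalized vector
  v <- list(r1 = r1, r2 = r2)
  nrm <- sqrt(rrcc3:::eom_dot(v, v))
  vv <- eom_vector(r1 / nrm, r2 / nrm)
  p2 <- percent_r2(vv)
  p1 <- 100 * sum(vv$r1^2) / rrcc3:::eom_dot(vv, vv)
  expect_equal(p1 + p2, 100, tolerance = 1e-10)
  expect_warning(percent_r2(eom_vector(2 * vv$r1, 2 * vv$r2)), "renormaliz")
})

test_that("root homing survives a near-degenerate pair at tight thresholds", {
  fx <- fix_medium()
  cc <- solve_ccsd(spin_orbital_basis(fx$ints, fx$spaces))
  r <- solve_eom_ccsd(fx$ints, fx$spaces, cc, n_roots = 1L,
                      conv_energy = 1e-7, conv_residual = 1e-6)
  # the root stays in the physical window near its CIS parent
  env <- eom_env(fx$ints, fx$spaces, cc)
  g <- cis_guess(env, 1L)[[1]]
  expect_gt(r[[1]]$omega, 0)
  expect_lt(abs(r[[1]]$omega - g$omega), 0.2)
})
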