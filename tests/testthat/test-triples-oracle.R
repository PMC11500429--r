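# Dense triples oracle: triples equations verified against determinant-space
# commutators, and basic structure of the oracle operations.

test_that("Tucker reconstruction and projection are exact inverses at full
           rank and preserve pair symmetry", {
  O <- 2L; V <- 3L; nov <- 6L
  set.seed(41)
  Vp <- qr.Q(qr(matrix(rnorm(nov * 4), nov, 4)))
  core <- array(rnorm(64), dim = c(4, 4, 4))
  core <- local({ s <- 0
    for (p in rrcc3:::.p3_perms) s <- s + aperm(core, p); s })
  w <- reconstruct_tucker(core, Vp, O, V)
  expect_lt(amax(w - symmetrize_p3(w) / 6), 1e-12)
  Vf <- diag(nov)
  cf <- project_triples(w, Vf, O, V)
  expect_lt(amax(reconstruct_tucker(cf, Vf, O, V) - w), 1e-12)
  expect_equal(reconstruct_tucker(0 * core, Vp, O, V),
               array(0, dim = c(O, O, O, V, V, V)))
})

test_that("the dense generator vanishes without amplitudes and is linear", {
  ds <- dressed_small()
  z <- dense_gamma(0 * ds$t2sp, ds$gt, 2L, 3L)
  expect_equal(amax(z), 0)
  g1 <- dense_gamma(ds$t2sp, ds$gt, 2L, 3L)
  g2 <- dense_gamma(2 * ds$t2sp, ds$gt, 2L, 3L)
  expect_lt(amax(g2 - 2 * g1), 1e-13)
})

test_that("the ground-state triples equation holds in determinant space", {
  fx <- fix_small(); O <- 2L; V <- 3L
  cc <- ccsd_small(); ds <- dressed_small()
  gam <- dense_gamma(ds$t2sp, ds$gt, O, V)
  t3 <- solve_dense_r3(gam, fx$spaces$eps_occ, fx$spaces$eps_virt, omega = 0)
  expect_lt(amax(t3 - symmetrize_p3(t3) / 6), 1e-11)
  bas <- det_basis(5L, 2L)
  epsso <- c(rep(fx$spaces$eps_occ, 2), rep(fx$spaces$eps_virt, 2))
  Fdet <- rrcc3:::det_onebody(bas, diag(epsso))
  Htd <- rrcc3:::det_general_hamiltonian(bas, ds$dr$h, ds$gt)
  T2m <- rrcc3:::det_t2_matrix(bas, cc$t2)
  T3m <- rrcc3:::det_t3_matrix(bas, t3)
  res <- ((Htd %*% T2m - T2m %*% Htd) +
            (Fdet %*% T3m - T3m %*% Fdet))[, bas$ref]
  expect_lt(amax(res[bas$rank == 3]), 1e-10)
})

test_that("the excited-state triples equation (with the R1 derivative terms)
           holds in determinant space", {
  fx <- fix_small(); O <- 2L; V <- 3L
  cc <- ccsd_small(); ds <- dressed_small()
  set.seed(21)
  c1r <- matrix(rnorm(O * V), O, V)
  c2r <- rand_d2(O, V, 77)
  omega <- 0.7
  dd <- dress_derivative(ds$dr, fx$ints$h, c1r)
  n <- 5L
  Wp <- local({
    B <- matrix(ds$dr$b, n * n, ds$dr$n_aux)
    dB <- matrix(dd$b, n * n, dd$n_aux)
    array(B %*% t(dB) + dB %*% t(B), dim = c(n, n, n, n))
  })
  gam <- dense_gamma(c2r, ds$gt, O, V) + dense_gamma(ds$t2sp, Wp, O, V)
  r3 <- solve_dense_r3(gam, fx$spaces$eps_occ, fx$spaces$eps_virt,
                       omega = omega)
  bas <- det_basis(5L, 2L)
  epsso <- c(rep(fx$spaces$eps_occ, 2), rep(fx$spaces$eps_virt, 2))
  Fdet <- rrcc3:::det_onebody(bas, diag(epsso))
  Htd <- rrcc3:::det_general_hamiltonian(bas, ds$dr$h, ds$gt)
  T2m <- rrcc3:::det_t2_matrix(bas, cc$t2)
  R1m <- rrcc3:::det_t1_matrix(bas, rrcc3:::singlet_r1_so(c1r))
  R2m <- rrcc3:::det_t2_matrix(bas, rrcc3:::singlet_r2_so(c2r))
  R3m <- rrcc3:::det_t3_matrix(bas, r3)
  HT2 <- Htd %*% T2m - T2m %*% Htd
  res <- ((Htd %*% R2m - R2m %*% Htd) +
            (HT2 %*% R1m - R1m %*% HT2) +
            (Fdet %*% R3m - R3m %*% Fdet) - omega * R3m)[, bas$ref]
  expect_lt(amax(res[bas$rank == 3]), 1e-10)
})

test_that("sigma contributions of a triples operator match determinant-space
           commutators for seeded random tensors", {
  fx <- fix_small(); O <- 2L; V <- 3L
  ds <- dressed_small()
  bas <- det_basis(5L, 2L)
  Htd <- rrcc3:::det_general_hamiltonian(bas, ds$dr$h, ds$gt)
  Fov <- ds$dr$fock[1:O, O + 1:V, drop = FALSE]
  for (seed in c(55, 56)) {
    w <- rand_w3(O, V, seed)
    R3m <- rrcc3:::det_t3_matrix(bas, w)
    targ <- (Htd %*% R3m - R3m %*% Htd)[, bas$ref]
    sg <- dense_sigma_triples(w, ds$gt, Fov, O, V)
    v1 <- rrcc3:::det_t1_matrix(bas, rrcc3:::singlet_r1_so(sg$s1))[, bas$ref]
    v2 <- rrcc3:::det_t2_matrix(bas, rrcc3:::singlet_r2_so(sg$s2))[, bas$ref]
    expect_lt(amax(v1[bas$rank == 1] - targ[bas$rank == 1]), 1e-11)
    expect_lt(amax(v2[bas$rank == 2] - targ[bas$rank == 2]), 1e-11)
  }
  # zero triples give zero contributions; the functional is linear
  z <- dense_sigma_triples(0 * rand_w3(O, V, 1), ds$gt, Fov, O, V)
  expect_equal(amax(z$s1), 0)
  expect_equal(amax(z$s2), 0)
})

test_that("substituting the solved triples back into the residual gives zero
           (element-wise residual check)", {
  fx <- fix_small(); O <- 2L; V <- 3L
  ds <- dressed_small()
  gam <- dense_gamma(ds$t2sp, ds$gt, O, V)
  omega <- 0.3
  r3 <- solve_dense_r3(gam, fx$spaces$eps_occ, fx$spaces$eps_virt, omega)
  D <- rrcc3:::triples_denominator(fx$spaces$eps_occ, fx$spaces$eps_virt)
  res <- (omega - D) * r3 - symmetrize_p3(gam)
  expect_lt(amax(res), 1e-10)
})

test_that("the oracle refuses systems beyond its size guard", {
  expect_error(reconstruct_tucker(array(0, c(1, 1, 1)), matrix(1, 45, 1),
                                  9L, 5L), "guard")
})
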