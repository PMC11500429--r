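# Term-wise equivalence of the factorized (rank-reduced) triples operations
# with naive dense contractions over Tucker-reconstructed tensors, across
# seeded random inputs and space sizes.

.random_setup <- function(O, V, seed) {
  fx <- synth_hamiltonian(O, V, seed = seed, interaction_scale = 0.12)
  df <- cholesky_factorize(fx$ints, tol = 1e-12)
  set.seed(seed + 1000L)
  t1 <- matrix(rnorm(O * V, sd = 0.05), O, V)
  dr <- dress_t1(df, fx$ints$h, t1, O)
  gt <- dressed_eri(dr)
  nov <- O * V
  N <- sample(2:nov, 1)
  Vp <- qr.Q(qr(matrix(rnorm(nov * N), nov, N)))
  core <- array(rnorm(N^3), dim = c(N, N, N))
  core <- local({ s <- 0
    for (p in rrcc3:::.p3_perms) s <- s + aperm(core, p); s })
  list(fx = fx, df = df, dr = dr, gt = gt, Vp = Vp, core = core,
       d2 = rand_d2(O, V, seed + 2000L), O = O, V = V, N = N)
}

test_that("factorized sigma contributions equal dense contractions with the
           reconstructed triples for >= 20 seeded inputs", {
  cases <- expand.grid(seed = 1:7, dim = 1:3)
  sizes <- list(c(2L, 3L), c(3L, 4L), c(3L, 5L))
  for (r in seq_len(nrow(cases))) {
    sz <- sizes[[cases$dim[r]]]
    st <- .random_setup(sz[1], sz[2], 100L + 13L * r)
    O <- st$O; V <- st$V
    w <- reconstruct_tucker(st$core, st$Vp, O, V)
    Fov <- st$dr$fock[1:O, O + 1:V, drop = FALSE]
    dense <- dense_sigma_triples(w, st$gt, Fov, O, V)
    Bp <- list(list(st$dr$b, st$dr$b))
    s1 <- sigma1_from_core(st$core, st$Vp, Bp, O, V)
    s2 <- sigma2_from_core(st$core, st$Vp, Bp, Fov, O, V)
    expect_lt(amax(s1 - dense$s1), 1e-10)
    expect_lt(amax(s2 - dense$s2), 1e-10)
  }
})

test_that("the projected generator (core equation input) equals the dense
           projection for >= 20 seeded inputs, including the derivative
           (R1-dependent) integrals", {
  for (r in 1:21) {
    sz <- list(c(2L, 3L), c(3L, 4L), c(3L, 5L))[[1L + (r %% 3L)]]
    st <- .random_setup(sz[1], sz[2], 300L + 17L * r)
    O <- st$O; V <- st$V
    # plain dressed integrals
    gd <- project_triples(dense_gamma(st$d2, st$gt, O, V), st$Vp, O, V)
    gf <- gamma_projected(st$d2, list(list(st$dr$b, st$dr$b)), st$Vp, O, V)
    expect_lt(amax(gf - gd), 1e-10)
    # derivative-dressed integrals of [H~, R1]
    set.seed(400L + r)
    r1 <- matrix(rnorm(O * V), O, V)
    dd <- dress_derivative(st$dr, st$fx$ints$h, r1)
    n <- O + V
    Wp <- local({
      B <- matrix(st$dr$b, n * n, st$dr$n_aux)
      dB <- matrix(dd$b, n * n, dd$n_aux)
      array(B %*% t(dB) + dB %*% t(B), dim = c(n, n, n, n))
    })
    gdp <- project_triples(dense_gamma(st$d2, Wp, O, V), st$Vp, O, V)
    gfp <- gamma_projected(st$d2, list(list(st$dr$b, dd$b),
                                       list(dd$b, st$dr$b)), st$Vp, O, V)
    expect_lt(amax(gfp - gdp), 1e-10)
  }
})

test_that("the core tensor is fully permutation-symmetric and matches the
           dense solve-and-project route", {
  st <- .random_setup(3L, 4L, 999L)
  O <- st$O; V <- st$V
  eps_o <- st$fx$spaces$eps_occ; eps_v <- st$fx$spaces$eps_virt
  can <- canonicalize_projector(st$Vp, eps_o, eps_v)
  omega <- 0.4
  gh <- gamma_projected(st$d2, list(list(st$dr$b, st$dr$b)), can$v, O, V)
  core <- compute_core(gh, can$eps, omega = omega)
  for (p in rrcc3:::.p3_perms)
    expect_lt(amax(core - aperm(core, p)), 1e-10)
  # oracle route: project the generator, then solve in the projected basis
  # with the canonical denominators (valid because the projected one-body
  # matrix is diagonal in the canonical basis)
  gam <- dense_gamma(st$d2, st$gt, O, V)
  ghd <- project_triples(gam, can$v, O, V)
  sym <- 0
  for (p in rrcc3:::.p3_perms) sym <- sym + aperm(ghd, p)
  den <- omega - outer(outer(can$eps, can$eps, "+"), can$eps, "+")
  expect_lt(amax(core - sym / den), 1e-10)
  # zero doubles give a zero core
  z <- compute_core(gamma_projected(0 * st$d2, list(list(st$dr$b, st$dr$b)),
                                    can$v, O, V), can$eps, omega)
  expect_equal(amax(z), 0)
})

test_that("the intruder-state guard reports the offending denominator", {
  st <- .random_setup(2L, 3L, 123L)
  can <- canonicalize_projector(st$Vp, st$fx$spaces$eps_occ,
                                st$fx$spaces$eps_virt)
  gh <- gamma_projected(st$d2, list(list(st$dr$b, st$dr$b)), can$v, 2L, 3L)
  omega_bad <- 3 * can$eps[1]     # hits the lowest canonical denominator
  expect_error(compute_core(gh, can$eps, omega = omega_bad),
               "near-singular")
})

test_that("the Laplace provider reproduces dense partial projections of the
           guess tensor, with and without a shift", {
  for (r in 1:6) {
    sz <- list(c(2L, 3L), c(3L, 4L))[[1L + (r %% 2L)]]
    st <- .random_setup(sz[1], sz[2], 500L + 31L * r)
    O <- st$O; V <- st$V; nov <- O * V
    eps_o <- st$fx$spaces$eps_occ; eps_v <- st$fx$spaces$eps_virt
    shift <- if (r %% 2L) 0 else 0.35
    prov <- pt_triples_provider(st$d2, st$dr$b, eps_o, eps_v, shift = shift)
    M <- solve_dense_r3(dense_gamma(st$d2, st$gt, O, V), eps_o, eps_v,
                        omega = shift)
    dp <- dense_provider(M, O, V)
    set.seed(600L + r)
    Vy <- qr.Q(qr(matrix(rnorm(nov * 3), nov, 3)))
    Vz <- qr.Q(qr(matrix(rnorm(nov * 2), nov, 2)))
    Rf <- prov(Vy, Vz)
    Rd <- dp(Vy, Vz)
    expect_lt(amax(Rf - Rd) / max(amax(Rd), 1e-10), 1e-5)
  }
})

test_that("providers are linear in their doubles input and vanish for zero
           doubles", {
  st <- .random_setup(2L, 3L, 777L)
  eps_o <- st$fx$spaces$eps_occ; eps_v <- st$fx$spaces$eps_virt
  nov <- 6L
  set.seed(7)
  Vy <- qr.Q(qr(matrix(rnorm(nov * 2), nov, 2)))
  p1 <- pt_triples_provider(st$d2, st$dr$b, eps_o, eps_v)
  p2 <- pt_triples_provider(2 * st$d2, st$dr$b, eps_o, eps_v)
  p0 <- pt_triples_provider(0 * st$d2, st$dr$b, eps_o, eps_v)
  expect_lt(amax(p2(Vy, Vy) - 2 * p1(Vy, Vy)), 1e-12)
  expect_equal(amax(p0(Vy, Vy)), 0)
})

test_that("no rank-6 tensor can slip through the contraction engine", {
  big <- array(0, dim = rep(2, 6))
  ops <- list(list(a = big, lab = "abcdef"),
              list(a = array(0, rep(2, 6)), lab = "ghijkl"))
  expect_error(rrcc3:::tn_contract(ops, "abcdefghijkl"), "order|guard|path")
})

test_that("the excited provider reduces to the ground provider at zero shift
           and equal doubles", {
  st <- .random_setup(2L, 3L, 888L)
  eps_o <- st$fx$spaces$eps_occ; eps_v <- st$fx$spaces$eps_virt
  set.seed(10)
  Vy <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  pg <- pt_triples_provider(st$d2, st$dr$b, eps_o, eps_v)
  pe <- excited_triples_provider(st$d2, 0, st$dr$b, eps_o, eps_v)
  expect_lt(amax(pg(Vy, Vy) - pe(Vy, Vy)), 1e-13)
})
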