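# FCIDUMP input/output, factorization and T1 dressing of the integrals.

test_that("FCIDUMP files round-trip bit-exactly and validate their headers", {
  fx <- fix_small()
  path <- withr::local_tempfile(fileext = ".fcidump")
  write_fcidump(fx$spaces, fx$ints, path)
  back <- read_fcidump(path)
  expect_equal(back$ints$h, fx$ints$h, tolerance = 0)
  expect_equal(back$ints$g, fx$ints$g, tolerance = 0)
  expect_identical(back$ints$n_electrons, fx$ints$n_electrons)
  expect_equal(back$spaces$eps_occ, fx$spaces$eps_occ, tolerance = 1e-12)

  # orbital energies may alternatively be taken from the file records
  rec <- read_fcidump(path, energies_from = "records")
  expect_equal(rec$spaces$eps_virt, fx$spaces$eps_virt, tolerance = 0)

  # writer emits exactly the symmetry-unique nonzero two-electron records
  lines <- readLines(path)
  two_el <- grep("^[0-9+-].* [1-9][0-9]* [1-9][0-9]* [1-9][0-9]* [1-9][0-9]*$",
                 lines)
  expect_length(two_el, count_unique_eri(fx$ints$g))

  # malformed header and odd electron count are rejected with clear errors
  bad <- withr::local_tempfile()
  writeLines(c(" &FCI NELEC=4,", " &END", "1.0 1 1 1 1"), bad)
  expect_error(read_fcidump(bad), "NORB")
  odd <- withr::local_tempfile()
  writeLines(c(" &FCI NORB=2,NELEC=3,", " &END", "0.5 1 1 0 0"), odd)
  expect_error(read_fcidump(odd), "odd|closed-shell")
})

test_that("a zero two-electron interaction reads back as a Fock-only problem", {
  fx <- synth_hamiltonian(2, 2, seed = 5, interaction_scale = 0)
  path <- withr::local_tempfile()
  write_fcidump(fx$spaces, fx$ints, path)
  back <- read_fcidump(path)
  expect_true(all(back$ints$g == 0))
  so <- spin_orbital_basis(back$ints, back$spaces)
  cc <- solve_ccsd(so)
  expect_equal(cc$e_corr, 0, tolerance = 1e-14)
})

test_that("pivoted Cholesky reconstructs the integrals within tolerance", {
  fx <- fix_small()
  df <- cholesky_factorize(fx$ints, tol = 1e-8)
  err <- amax(df_reconstruct(df) - fx$ints$g)
  expect_lt(err, 1e-8)
  expect_lte(df$n_aux, fx$ints$n_mo^2)
  # reconstruction error is non-increasing in the number of vectors
  errs <- vapply(seq_len(df$n_aux), function(k) {
    dk <- df_factors(df$b[, , seq_len(k), drop = FALSE])
    amax(df_reconstruct(dk) - fx$ints$g)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  # 8-fold symmetry survives the factorization
  expect_lt(rrcc3:::max_asym8(df_reconstruct(df)), 1e-10)
})

test_that("rank-1 and zero interactions factorize to the expected rank", {
  n <- 3
  gvec <- matrix(rnorm(n * n), n); gvec <- (gvec + t(gvec)) / 2
  g1 <- outer(gvec, gvec)
  h <- diag(c(-1, 0.5, 1.0))
  # rank-1 case needs a Hamiltonian wrapper without the canonical check
  ints1 <- mo_integrals(h, g1, n_electrons = 2L, check = FALSE)
  df1 <- cholesky_factorize(ints1, tol = 1e-10)
  expect_identical(df1$n_aux, 1L)
  ints0 <- mo_integrals(h, array(0, dim = rep(n, 4)), n_electrons = 2L)
  expect_identical(cholesky_factorize(ints0)$n_aux, 0L)
})

test_that("metric-based density fitting matches the dense metric inverse", {
  set.seed(8)
  n <- 3; na <- 3
  tc <- array(rnorm(n * n * na), dim = c(n, n, na))
  tc <- (tc + aperm(tc, c(2, 1, 3))) / 2
  expect_equal(build_df_factors(tc, diag(na))$b, tc, tolerance = 1e-13)
  d <- c(0.5, 2, 4)
  bd <- build_df_factors(tc, diag(d))$b
  expect_equal(bd, sweep(tc, 3, sqrt(d), "/"), tolerance = 1e-13)
  A <- matrix(rnorm(na * na), na); S <- crossprod(A) + diag(na)
  b <- build_df_factors(tc, S)$b
  fitted <- ein2("pqQ,rsQ->pqrs", b, b)
  dense <- ein2("pqP,rsP->pqrs", ein2("pqR,RP->pqP", tc, solve(S)), tc)
  expect_equal(fitted, dense, tolerance = 1e-10)
  expect_error(build_df_factors(tc, -S), "positive definite")
})

test_that("T1 dressing is exact, invertible and matches its derivative", {
  ds <- dressed_small(); fx <- fix_small()
  O <- 2L; V <- 3L
  # t1 = 0 is the identity
  dz <- dress_t1(ds$df, fx$ints$h, matrix(0, O, V), O)
  expect_equal(dz$b, ds$df$b, tolerance = 0)
  expect_equal(dz$fock, fock_matrix(fx$ints, O), tolerance = 1e-12)
  # dressing by -t1 undoes dressing by t1
  undo <- dress_t1(df_factors(ds$dr$b), ds$dr$h, -ds$t1sp, O)
  expect_lt(amax(undo$b - ds$df$b), 1e-12)
  # dense four-index transform agrees with the factor transform
  dd <- rrcc3:::dress_dense(fx$ints$h, fx$ints$g, ds$t1sp, O)
  expect_lt(amax(dd$g - ds$gt), 1e-12)
  expect_lt(amax(dd$fock - ds$dr$fock), 1e-12)
  # directional derivative matches central finite differences
  set.seed(12)
  r1 <- matrix(rnorm(O * V, sd = 0.05), O, V)
  eps <- 1e-6
  dp <- dress_t1(ds$df, fx$ints$h, ds$t1sp + eps * r1, O)
  dm <- dress_t1(ds$df, fx$ints$h, ds$t1sp - eps * r1, O)
  dv <- dress_derivative(ds$dr, fx$ints$h, r1)
  expect_lt(amax((dp$b - dm$b) / (2 * eps) - dv$b), 1e-8)
  expect_lt(amax((dp$fock - dm$fock) / (2 * eps) - dv$fock), 1e-7)
})

test_that("dressing composes: dress(t1) then dress(t1') equals dress(t1+t1')", {
  fx <- fix_tiny(); O <- 1L; V <- 2L
  df <- cholesky_factorize(fx$ints, tol = 1e-12)
  set.seed(3)
  ta <- matrix(rnorm(O * V, sd = 0.1), O, V)
  tb <- matrix(rnorm(O * V, sd = 0.1), O, V)
  d1 <- dress_t1(df, fx$ints$h, ta, O)
  d2 <- dress_t1(df_factors(d1$b), d1$h, tb, O)
  d12 <- dress_t1(df, fx$ints$h, ta + tb, O)
  expect_lt(amax(d2$b - d12$b), 1e-12)
})

test_that("freezing core orbitals folds their mean field into the core", {
  fx <- fix_small()
  same <- select_frozen_core(fx$spaces, fx$ints, 0L)
  expect_identical(same$spaces$n_occ, fx$spaces$n_occ)
  fc <- select_frozen_core(fx$spaces, fx$ints, 1L)
  expect_identical(fc$spaces$n_occ, 1L)
  expect_identical(fc$spaces$n_mo, fx$spaces$n_mo - 1L)
  # independent fold-in oracle: explicit loops over the frozen orbital
  n <- fx$ints$n_mo; g <- fx$ints$g; h <- fx$ints$h
  act <- 2:n
  h_eff <- matrix(0, n - 1, n - 1)
  for (p in act) for (q in act)
    h_eff[p - 1, q - 1] <- h[p, q] + 2 * g[p, q, 1, 1] - g[p, 1, 1, q]
  expect_equal(fc$ints$h, h_eff, tolerance = 1e-12)
  e_core <- 2 * h[1, 1] + 2 * g[1, 1, 1, 1] - g[1, 1, 1, 1]
  expect_equal(fc$ints$e_core, fx$ints$e_core + e_core, tolerance = 1e-12)
  # the HF energy is invariant under the fold-in
  expect_equal(hf_energy(fc$ints, 1L), hf_energy(fx$ints, 2L),
               tolerance = 1e-10)
  expect_error(select_frozen_core(fx$spaces, fx$ints, 2L), "range")
})

test_that("the backend adapter reconstructs density-fitted Hamiltonians", {
  fx <- fix_tiny()
  df <- cholesky_factorize(fx$ints, tol = 1e-12)
  provider <- list(eps = c(fx$spaces$eps_occ, fx$spaces$eps_virt),
                   h = fx$ints$h, three_center = df$b,
                   metric = diag(df$n_aux),
                   n_electrons = fx$ints$n_electrons)
  imp <- backend_import(provider)
  expect_equal(imp$ints$g, fx$ints$g, tolerance = 1e-10)
  expect_identical(imp$spaces$n_occ, fx$spaces$n_occ)
  expect_error(backend_import(provider[-2]), "lacks")
})
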