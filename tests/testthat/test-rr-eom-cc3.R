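# RR-EOM-CC3: full-rank equivalence with the dense oracle, degenerate limits
# and the self-consistent folding of the triples.

test_that("full-rank RR-EOM-CC3 matches the dense canonical EOM-CC3", {
  fx <- fix_small()
  pair <- cc3_small()
  guess <- eom_ccsd_small()[[1]]
  de <- solve_dense_eom_cc3(fx$ints, fx$spaces, pair$dense, guess,
                            conv_energy = 1e-7, conv_residual = 1e-6)
  rr <- solve_rr_eom_cc3(fx$ints, fx$spaces, pair$rr, guess, n_SVD = 6L,
                         conv_energy = 1e-7, conv_residual = 1e-6)
  expect_lt(abs(de$omega - rr$omega), 1e-6)
  # the triples shift the excitation energy away from EOM-CCSD
  expect_gt(abs(de$omega - guess$omega), 1e-7)
  # delivered state keeps maximum overlap with the guess
  expect_gt(abs(rrcc3:::eom_dot(rr$vector, guess)), 0.9)
})

test_that("empty triple-excitation subspaces reduce to EOM-CCSD", {
  fx <- fix_small()
  gr0 <- solve_cc3_ground_rr(fx$ints, fx$spaces, n_svd = 0L)
  guess <- eom_ccsd_small()[[1]]
  rr0 <- solve_rr_eom_cc3(fx$ints, fx$spaces, gr0, guess, n_SVD = 0L,
                          conv_energy = 1e-8, conv_residual = 1e-7)
  expect_lt(abs(rr0$omega - guess$omega), 1e-6)
})

test_that("the delivered root satisfies the convergence contract", {
  fx <- fix_small()
  pair <- cc3_small()
  guess <- eom_ccsd_small()[[1]]
  rr <- solve_rr_eom_cc3(fx$ints, fx$spaces, pair$rr, guess, n_SVD = 4L,
                         conv_energy = 1e-5, conv_residual = 1e-4)
  expect_lt(rr$residual, 1e-4)
  if (length(rr$trace) >= 2)
    expect_lt(abs(diff(utils::tail(rr$trace, 2))), 1e-5)
  # omega is real and near the guess
  expect_lt(abs(rr$omega - guess$omega), 0.05)
})

test_that("the projected core is recomputed with the current omega (the
           folded triples are omega-dependent)", {
  fx <- fix_small()
  pair <- cc3_small()
  gr <- pair$rr
  ds <- dressed_small()
  can <- canonicalize_projector(diag(6), fx$spaces$eps_occ,
                                fx$spaces$eps_virt)
  gh <- gamma_projected(ds$t2sp, list(list(gr$dressed$b, gr$dressed$b)),
                        can$v, 2L, 3L)
  c1 <- compute_core(gh, can$eps, omega = 0.3)
  c2 <- compute_core(gh, can$eps, omega = 0.6)
  expect_gt(amax(c1 - c2), 1e-8)
})

test_that("the full pipeline runs end to end and reports consistent units", {
  fx <- fix_small()
  res <- run_rr_eom_cc3(fx$ints, fx$spaces, state = 1L, n_svd = 6L,
                        n_SVD = 6L)
  expect_equal(res$omega_ev, res$omega * hartree_to_ev(), tolerance = 1e-12)
  expect_true(res$percent_r2 >= 0 && res$percent_r2 <= 100)
  expect_identical(res$n_svd, 6L)
  # the rank policy accepts multiples of the molecular-orbital count
  expect_identical(resolve_rank("1.0*nmo", fx$spaces), 5L)
  expect_identical(resolve_rank("1.4*nmo", fx$spaces), 7L)
  expect_identical(resolve_rank(4L, fx$spaces), 4L)
})
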