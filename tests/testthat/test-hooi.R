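# HOOI, stacked-SVD damping and projector canonicalization.

.sym_core <- function(N, seed) {
  set.seed(seed)
  x <- array(rnorm(N^3), dim = c(N, N, N))
  s <- 0
  for (p in rrcc3:::.p3_perms) s <- s + aperm(x, p)
  s
}

test_that("an exact-rank tensor is recovered to machine precision", {
  O <- 2L; V <- 3L; nov <- 6L
  set.seed(9)
  Vp0 <- qr.Q(qr(matrix(rnorm(nov * 3), nov, 3)))
  w <- reconstruct_tucker(.sym_core(3L, 10L), Vp0, O, V)
  h <- hooi_decompose(dense_provider(w, O, V), 3L, nov, seed = 4L)
  rec <- reconstruct_tucker(project_triples(w, h$v, O, V), h$v, O, V)
  expect_lt(amax(rec - w), 1e-10)
  expect_lt(amax(t(h$v) %*% h$v - diag(3)), 1e-10)
})

test_that("the full pair space reproduces any tensor exactly", {
  O <- 2L; V <- 3L; nov <- 6L
  w <- rand_w3(O, V, 71)
  h <- hooi_decompose(dense_provider(w, O, V), nov, nov, seed = 2L)
  rec <- reconstruct_tucker(project_triples(w, h$v, O, V), h$v, O, V)
  expect_lt(amax(rec - w), 1e-10)
})

test_that("the captured-variance surrogate is non-decreasing over accepted
           iterates and HOOI does not lose to one-shot HOSVD", {
  O <- 2L; V <- 3L; nov <- 6L
  set.seed(12)
  Vp0 <- qr.Q(qr(matrix(rnorm(nov * 3), nov, 3)))
  w <- reconstruct_tucker(.sym_core(3L, 13L), Vp0, O, V) +
    0.05 * rand_w3(O, V, 14)
  h <- hooi_decompose(dense_provider(w, O, V), 3L, nov, seed = 5L)
  expect_true(all(diff(h$history) >= -1e-8 * max(abs(h$history))))
  rec <- reconstruct_tucker(project_triples(w, h$v, O, V), h$v, O, V)
  errH <- fnorm(rec - w)
  M <- aperm(w, c(1, 4, 2, 5, 3, 6)); dim(M) <- c(nov, nov * nov)
  U0 <- svd(M)$u[, 1:3]
  rec0 <- reconstruct_tucker(project_triples(w, U0, O, V), U0, O, V)
  expect_lte(errH, fnorm(rec0 - w) + 1e-10)
})

test_that("requested ranks beyond the pair dimension are clipped", {
  w <- rand_w3(2L, 3L, 3)
  expect_warning(h <- hooi_decompose(dense_provider(w, 2L, 3L), 10L, 6L),
                 "clipped")
  expect_identical(ncol(h$v), 6L)
})

test_that("stacked-SVD damping preserves orthonormality and span
           containment", {
  nov <- 6L
  set.seed(31)
  Va <- qr.Q(qr(matrix(rnorm(nov * 3), nov, 3)))
  Vb <- qr.Q(qr(matrix(rnorm(nov * 3), nov, 3)))
  Vd <- stacked_svd_damping(Va, Vb)
  expect_lt(amax(t(Vd) %*% Vd - diag(3)), 1e-10)
  # residual of the projection onto span([Va Vb]) built densely
  P <- cbind(Va, Vb)
  Pp <- P %*% solve(t(P) %*% P, t(P))
  expect_lt(amax(Vd - Pp %*% Vd), 1e-10)
  # idempotent span: damping a projector with itself keeps its span
  Vs <- stacked_svd_damping(Va, Va)
  expect_lt(amax(Vs %*% t(Vs) - Va %*% t(Va)), 1e-10)
  expect_error(stacked_svd_damping(cbind(Va[, 1], Va[, 1]),
                                   cbind(Va[, 1], Va[, 1])),
               "rank deficient")
})

test_that("canonicalization diagonalizes the projected one-body matrix and
           keeps the span", {
  nov <- 6L
  eps_o <- c(-1.4, -1.1); eps_v <- c(0.2, 0.5, 0.8)
  set.seed(8)
  Va <- qr.Q(qr(matrix(rnorm(nov * 4), nov, 4)))
  can <- canonicalize_projector(Va, eps_o, eps_v)
  delta <- as.numeric(outer(-eps_o, eps_v, "+"))
  G <- t(can$v) %*% (can$v * delta)
  expect_lt(amax(G - diag(can$eps)), 1e-10)
  expect_false(is.unsorted(can$eps))
  expect_lt(amax(can$v %*% t(can$v) - Va %*% t(Va)), 1e-10)
  # an already canonical projector is unchanged up to column signs
  again <- canonicalize_projector(can$v, eps_o, eps_v)
  expect_lt(amax(abs(again$v) - abs(can$v)), 1e-10)
})
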