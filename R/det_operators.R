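# Operator algebra over the determinant basis.
#
# Builds matrices of excitation operators (T1, T2, spatial-orbital triples)
# and of one/two-body Hamiltonians over the Sz = 0 determinant basis, plus a
# nilpotent matrix exponential.  Together with det_operator_matrix() this
# yields similarity-transformed Hamiltonians e^(-T) H e^(T) numerically,
# against which every hand-coded working equation in the package is tested.

#' Determinant basis with excitation-rank bookkeeping
#'
#' @param n_spatial number of spatial orbitals; @param n_occ doubly occupied.
#' @return list: \code{dets}, \code{rank} (excitation level of each
#'   determinant relative to the closed-shell reference), \code{ref} (index of
#'   the reference), \code{map} (determinant-ordering spin-orbital index for
#'   each CC-ordering spin orbital).
#' @export
det_basis <- function(n_spatial, n_occ) {
  dets <- enumerate_dets(n_spatial, n_occ, n_occ)
  ref_det <- sort(c(seq_len(n_occ), n_spatial + seq_len(n_occ)))
  rank <- vapply(dets, function(d) length(setdiff(d, ref_det)), integer(1))
  ref <- which(vapply(dets, function(d) all(d == ref_det), logical(1)))
  map <- .cc_to_det_map(n_occ, n_spatial - n_occ)
  list(dets = dets, rank = rank, ref = ref, map = map,
       n_spatial = n_spatial, n_occ = n_occ)
}

# one-body operator matrix from CC-ordering coefficients c[p,q] (creation p,
# annihilation q over the no+nv spin orbitals)
det_onebody <- function(basis, c_cc) {
  nso <- 2L * basis$n_spatial
  h1 <- matrix(0, nso, nso)
  h1[basis$map, basis$map] <- c_cc
  det_operator_matrix(basis$dets, h1)
}

# two-body operator with antisymmetrized CC-ordering coefficients
det_twobody <- function(basis, a_cc) {
  nso <- 2L * basis$n_spatial
  a2 <- array(0, dim = rep(nso, 4))
  a2[basis$map, basis$map, basis$map, basis$map] <- a_cc
  det_operator_matrix(basis$dets, matrix(0, nso, nso), a2)
}

# T1 operator matrix from spin-orbital t1[i,a] (CC ordering)
det_t1_matrix <- function(basis, t1, so) {
  no <- nrow(t1); nv <- ncol(t1)
  c_cc <- matrix(0, no + nv, no + nv)
  c_cc[no + seq_len(nv), seq_len(no)] <- t(t1)   # a+_a a_i
  det_onebody(basis, c_cc)
}

# T2 operator matrix from antisymmetric spin-orbital t2[i,j,a,b]
det_t2_matrix <- function(basis, t2) {
  no <- dim(t2)[1]; nv <- dim(t2)[3]; n <- no + nv
  a_cc <- array(0, dim = rep(n, 4))
  a_cc[no + seq_len(nv), no + seq_len(nv), seq_len(no), seq_len(no)] <-
    tperm("ijab->abij", t2)
  det_twobody(basis, a_cc)
}

# spatial singlet excitation operator E_ai = sum_sigma a+_{a sigma} a_{i sigma}
# as a determinant matrix; i, a are ACTIVE spatial indices (i occupied block,
# a virtual block)
det_E_matrix <- function(basis, i, a) {
  n <- basis$n_spatial; O <- basis$n_occ
  no <- 2L * O; nv <- 2L * (n - O)
  c_cc <- matrix(0, no + nv, no + nv)
  # alpha: occ slot i, virt slot a; beta: offsets O and (n-O)
  c_cc[no + a, i] <- 1
  c_cc[no + (n - O) + a, O + i] <- 1
  det_onebody(basis, c_cc)
}

# triples operator from a spatial pair-symmetric tensor w[i,j,k,a,b,c]:
# T3 = (1/6) sum w_ijk^abc E_ai E_bj E_ck (the 1/6 compensates the six-fold
# pair-permutation redundancy of a symmetric w)
det_t3_matrix <- function(basis, w) {
  O <- basis$n_occ; V <- basis$n_spatial - O
  nd <- length(basis$dets)
  Es <- vector("list", O * V)
  for (i in seq_len(O)) for (a in seq_len(V))
    Es[[(a - 1L) * O + i]] <- det_E_matrix(basis, i, a)
  Tm <- matrix(0, nd, nd)
  for (i in seq_len(O)) for (j in seq_len(O)) for (k in seq_len(O))
    for (a in seq_len(V)) for (b in seq_len(V)) for (c in seq_len(V)) {
      wv <- w[i, j, k, a, b, c]
      if (wv != 0)
        Tm <- Tm + (wv / 6) * Es[[(a - 1L) * O + i]] %*%
          Es[[(b - 1L) * O + j]] %*% Es[[(c - 1L) * O + k]]
    }
  Tm
}

# matrix exponential of a nilpotent operator (cluster operators truncate)
expm_nilpotent <- function(M, tol = 0) {
  out <- diag(nrow(M)); term <- diag(nrow(M)); k <- 0
  repeat {
    k <- k + 1
    term <- (term %*% M) / k
    if (amax(term) <= tol || k > 60) break
    out <- out + term
  }
  out
}

# Hamiltonian matrix over the basis from mo_integrals (normal-ordered:
# subtracts the reference expectation so the reference row/column carry the
# correlation part only when similarity transformed)
det_hamiltonian <- function(basis, ints, normal_ordered = TRUE) {
  n <- basis$n_spatial
  spat <- c(seq_len(n), seq_len(n))
  spin <- c(rep(1L, n), rep(-1L, n))
  same <- outer(spin, spin, "==") * 1.0
  h1 <- ints$h[spat, spat] * same
  gso <- ints$g[spat, spat, spat, spat] * outer(same, same)
  a2 <- aperm(gso, c(1, 3, 2, 4)) - aperm(gso, c(1, 3, 4, 2))
  H <- det_operator_matrix(basis$dets, h1, a2)
  if (normal_ordered) H <- H - diag(H[basis$ref, basis$ref], nrow(H))
  H
}

# Hamiltonian-like operator from general spatial chemist integrals (h, g) --
# used for dressed and derivative-dressed operators.  g need not have bra-ket
# symmetry; only the (pq)<->(rs) pair-exchange symmetry is assumed.
det_general_hamiltonian <- function(basis, h, g, subtract_ref = TRUE) {
  n <- basis$n_spatial
  spat <- c(seq_len(n), seq_len(n))
  spin <- c(rep(1L, n), rep(-1L, n))
  same <- outer(spin, spin, "==") * 1.0
  h1 <- h[spat, spat] * same
  gso <- g[spat, spat, spat, spat] * outer(same, same)
  a2 <- aperm(gso, c(1, 3, 2, 4)) - aperm(gso, c(1, 3, 4, 2))
  H <- det_operator_matrix(basis$dets, h1, a2)
  if (subtract_ref) H <- H - diag(H[basis$ref, basis$ref], nrow(H))
  H
}
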