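# Determinant-space reference machinery.
#
# These routines build many-electron Hamiltonian (and general one/two-body
# operator) matrices over Slater determinants represented as bit masks of
# spin orbitals.  They are deliberately naive - explicit Slater-Condon rules,
# dense matrices, full diagonalization - and share no code with the
# coupled-cluster tensor path, so agreement between the two is evidence of
# correctness rather than tautology.  Sizes are guarded: these are oracles for
# small fixtures, not production routines.

.det_guard <- 4000L

# enumerate all determinants with na alpha and nb beta electrons over nso/2
# spatial orbitals, as integer vectors of occupied spin-orbital indices.
# Spin-orbital ordering matches spin_orbital_basis(): occ-a, occ-b, virt-a,
# virt-b is NOT used here; instead this module uses its own ordering
# alpha-spatial-1..n, beta-spatial-1..n and converts at the interface.
enumerate_dets <- function(n_spatial, na, nb) {
  ca <- utils::combn(n_spatial, na, simplify = FALSE)
  cb <- utils::combn(n_spatial, nb, simplify = FALSE)
  out <- vector("list", length(ca) * length(cb))
  k <- 0L
  for (A in ca) for (B in cb) {
    k <- k + 1L
    out[[k]] <- c(A, n_spatial + B)   # beta block offset by n_spatial
  }
  out
}

# occupation bit vector for a determinant
.occ_vec <- function(det, nso) {
  v <- logical(nso); v[det] <- TRUE; v
}

# sign of bringing determinant (sorted occupied list) excitation q -> p
# relative to the ordered product convention
.exc_sign <- function(occ_sorted, p, q) {
  # remove q, insert p, count transpositions
  pos_q <- match(q, occ_sorted)
  rest <- occ_sorted[-pos_q]
  n_before_p <- sum(rest < p)
  n_before_q <- pos_q - 1L
  if ((n_before_p + n_before_q) %% 2L == 0L) 1 else -1
}

#' Build a many-body operator matrix over determinants
#'
#' Given spin-orbital one-body coefficients \code{h1[p,q]} (creation p,
#' annihilation q) and antisymmetrized two-body coefficients
#' \code{a2[p,q,r,s]} = coefficient of a+_p a+_q a_s a_r with
#' \code{a2} antisymmetric in (p,q) and (r,s) - i.e. <pq||rs>-like - returns
#' the dense matrix of H = sum h1 a+_p a_q + (1/4) sum a2 a+_p a+_q a_s a_r
#' over the determinant list via Slater-Condon rules.  Works for
#' non-Hermitian coefficient sets (needed for similarity-transformed and
#' dressed operators).
#'
#' @param dets list of sorted occupied spin-orbital index vectors.
#' @param h1 one-body coefficient matrix over spin orbitals.
#' @param a2 antisymmetrized two-body coefficient tensor over spin orbitals.
#' @keywords internal
det_operator_matrix <- function(dets, h1, a2 = NULL) {
  nso <- nrow(h1)
  nd <- length(dets)
  occm <- matrix(FALSE, nd, nso)
  for (i in seq_len(nd)) occm[i, dets[[i]]] <- TRUE
  H <- matrix(0, nd, nd)
  ne <- length(dets[[1]])
  for (J in seq_len(nd)) {           # ket
    dJ <- dets[[J]]
    oJ <- occm[J, ]
    for (I in seq_len(nd)) {         # bra
      diffIJ <- which(occm[I, ] & !oJ)   # in bra not in ket (created)
      diffJI <- which(oJ & !occm[I, ])   # in ket not in bra (annihilated)
      nex <- length(diffIJ)
      if (nex > 2L) next
      if (nex == 0L) {
        val <- sum(diag(h1)[dJ])
        if (!is.null(a2)) {
          for (m in dJ) for (n in dJ) val <- val + 0.5 * a2[m, n, m, n]
        }
        H[I, J] <- H[I, J] + val
      } else if (nex == 1L) {
        p <- diffIJ; q <- diffJI
        s <- .exc_sign(dJ, p, q)
        val <- h1[p, q]
        if (!is.null(a2)) {
          common <- setdiff(dJ, q)
          for (m in common) val <- val + a2[p, m, q, m]
        }
        H[I, J] <- H[I, J] + s * val
      } else if (nex == 2L && !is.null(a2)) {
        p <- diffIJ[1]; q <- diffIJ[2]   # created (sorted)
        r <- diffJI[1]; s2 <- diffJI[2]  # annihilated (sorted)
        # sign: apply r->p then s2->q sequentially
        sg <- .exc_sign(dJ, p, r)
        d1 <- sort(c(setdiff(dJ, r), p))
        sg <- sg * .exc_sign(d1, q, s2)
        H[I, J] <- H[I, J] + sg * a2[p, q, r, s2]
      }
    }
  }
  H
}

# spin-orbital index map between the CC ordering (occ-a, occ-b, virt-a,
# virt-b; see spin_orbital_basis) and the determinant ordering (alpha spatial
# 1..n, beta spatial 1..n).  Returns det_index[cc_index].
.cc_to_det_map <- function(O, V) {
  n <- O + V
  c(seq_len(O),                # occ alpha -> alpha spatial 1..O
    n + seq_len(O),            # occ beta
    O + seq_len(V),            # virt alpha
    n + O + seq_len(V))        # virt beta
}

#' Full configuration interaction reference
#'
#' Diagonalizes the electronic Hamiltonian in the complete determinant basis
#' with Sz = 0 (equal alpha and beta counts).  Returns total energies
#' (including the core offset) in ascending order, plus the determinant basis
#' and eigenvectors for downstream checks.
#'
#' @param ints \code{mo_integrals}.
#' @param n_roots number of eigenvalues to return (default all).
#' @export
fci_reference <- function(ints, n_roots = NULL) {
  n <- ints$n_mo
  npair <- ints$n_electrons %/% 2L
  dets <- enumerate_dets(n, npair, npair)
  if (length(dets) > .det_guard)
    stop("determinant space too large for the dense oracle (",
         length(dets), " > ", .det_guard, ")")
  nso <- 2L * n
  spat <- c(seq_len(n), seq_len(n))
  spin <- c(rep(1L, n), rep(-1L, n))
  h1 <- ints$h[spat, spat] * (outer(spin, spin, "==") * 1.0)
  same <- outer(spin, spin, "==") * 1.0
  gso <- ints$g[spat, spat, spat, spat] * outer(same, same)
  a2 <- aperm(gso, c(1, 3, 2, 4)) - aperm(gso, c(1, 3, 4, 2))
  H <- det_operator_matrix(dets, h1, a2)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- rev(ev$values) + ints$e_core
  vecs <- ev$vectors[, rev(seq_along(ev$values)), drop = FALSE]
  if (!is.null(n_roots)) {
    vals <- vals[seq_len(n_roots)]
    vecs <- vecs[, seq_len(n_roots), drop = FALSE]
  }
  list(energies = vals, dets = dets, vectors = vecs)
}
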