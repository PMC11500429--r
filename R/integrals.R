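#' Dense MO-basis Hamiltonian
#'
#' Container for a closed-shell molecular-orbital Hamiltonian: symmetric
#' one-electron matrix \code{h}, chemist-convention two-electron tensor
#' \code{g} with \code{g[p,q,r,s]} = (pq|rs) carrying full 8-fold permutational
#' symmetry, the electron count and a scalar core/nuclear-repulsion offset.
#' All values in hartree.
#'
#' @param h symmetric one-electron integral matrix.
#' @param g rank-4 two-electron integral array, chemist convention (pq|rs).
#' @param n_electrons even electron count (closed shell).
#' @param e_core scalar energy offset (nuclear repulsion + frozen core).
#' @param check validate symmetries (default TRUE).
#' @return object of class \code{mo_integrals}.
#' @export
mo_integrals <- function(h, g, n_electrons, e_core = 0, check = TRUE) {
  if (is.complex(h) || is.complex(g))
    stop("complex Hamiltonians are not supported (real arithmetic only)")
  n <- nrow(h)
  if (check) {
    if (amax(h - t(h)) > 1e-10) stop("one-electron matrix is not symmetric")
    if (!all(dim(g) == n)) stop("two-electron tensor dimension mismatch")
    if (max_asym8(g) > 1e-12 * max(1, amax(g)))
      stop("two-electron integrals lack 8-fold permutational symmetry")
  }
  if (n_electrons %% 2L != 0L)
    stop("odd electron count: only closed-shell references are supported")
  structure(list(h = h, g = g, n_electrons = as.integer(n_electrons),
                 e_core = as.numeric(e_core), n_mo = n),
            class = "mo_integrals")
}

#' @export
print.mo_integrals <- function(x, ...) {
  cat("mo_integrals: N_MO =", x$n_mo, " electrons =", x$n_electrons,
      " e_core =", format(x$e_core), "\n")
  invisible(x)
}

#' Closed-shell Fock matrix in the MO basis
#'
#' F = h + 2 J - K with the density of the first \code{n_occ} doubly occupied
#' orbitals.
#'
#' @param ints \code{mo_integrals}; @param n_occ doubly occupied count.
#' @export
fock_matrix <- function(ints, n_occ) {
  occ <- seq_len(n_occ)
  J <- apply(ints$g[, , occ, occ, drop = FALSE], c(1, 2),
             function(m) sum(diag(as.matrix(m))))
  K <- matrix(0, ints$n_mo, ints$n_mo)
  for (i in occ) K <- K + ints$g[, i, i, ]
  ints$h + 2 * J - K
}

#' Hartree-Fock energy of the closed-shell reference determinant
#' @param ints \code{mo_integrals}; @param n_occ doubly occupied count.
#' @export
hf_energy <- function(ints, n_occ) {
  occ <- seq_len(n_occ)
  e <- 2 * sum(diag(ints$h)[occ])
  for (i in occ) for (j in occ)
    e <- e + 2 * ints$g[i, i, j, j] - ints$g[i, j, j, i]
  e + ints$e_core
}

#' Derive orbital spaces from a Hamiltonian
#'
#' Builds the closed-shell Fock matrix, checks that the reference is canonical
#' (Fock diagonal to \code{tol}), and returns the \code{orbital_spaces} with
#' energies from the Fock diagonal.
#'
#' @param ints \code{mo_integrals}.
#' @param tol maximum tolerated off-diagonal Fock element.
#' @export
spaces_from_integrals <- function(ints, tol = 1e-8) {
  n_occ <- ints$n_electrons %/% 2L
  f <- fock_matrix(ints, n_occ)
  off <- amax(f - diag(diag(f)))
  if (off > tol)
    stop("reference is not canonical: max off-diagonal Fock element ",
         format(off))
  eps <- diag(f)
  orbital_spaces(n_occ, ints$n_mo - n_occ,
                 eps_occ = eps[seq_len(n_occ)],
                 eps_virt = eps[(n_occ + 1L):ints$n_mo])
}

# ---- spin-orbital expansion ------------------------------------------------
#
# Spin orbitals are ordered occupied-alpha, occupied-beta, virtual-alpha,
# virtual-beta; within each block the spatial order is kept.  The CCSD and
# EOM-CCSD stages work with the antisymmetrized spin-orbital integrals
# <pq||rs>; at the system sizes this package targets for verification these
# arrays are small enough to hold densely.

#' Spin-orbital blocks of the Hamiltonian
#'
#' Expands a spatial closed-shell Hamiltonian into spin-orbital quantities:
#' antisymmetrized two-electron integrals \code{aso[p,q,r,s]} = <pq||rs>
#' (physicist convention), the spin-orbital Fock diagonal, and index maps.
#'
#' @param ints \code{mo_integrals}; @param spaces \code{orbital_spaces}.
#' @return list with elements \code{aso}, \code{eps}, \code{no}, \code{nv},
#'   \code{spat} (spatial orbital of each spin orbital) and \code{spin}
#'   (+1/-1 for alpha/beta).
#' @export
spin_orbital_basis <- function(ints, spaces) {
  O <- spaces$n_occ; V <- spaces$n_virt; n <- O + V
  no <- 2L * O; nv <- 2L * V; nso <- no + nv
  # spatial index and spin of every spin orbital (occ a, occ b, virt a, virt b)
  spat <- c(seq_len(O), seq_len(O), O + seq_len(V), O + seq_len(V))
  spin <- c(rep(1L, O), rep(-1L, O), rep(1L, V), rep(-1L, V))
  g <- ints$g
  # chemist spin-orbital integrals: (PQ|RS) = (pq|rs) d(sP,sQ) d(sR,sS)
  same <- outer(spin, spin, "==") * 1.0
  gso <- g[spat, spat, spat, spat]
  gso <- gso * outer(same, same)       # [P,Q][R,S] spin deltas
  aso <- aperm(gso, c(1, 3, 2, 4)) - aperm(gso, c(1, 3, 4, 2))
  eps <- c(spaces$eps_occ, spaces$eps_occ, spaces$eps_virt, spaces$eps_virt)
  list(aso = aso, eps = eps, no = no, nv = nv, nso = nso,
       spat = spat, spin = spin, O = O, V = V)
}

# convenience: occupied / virtual spin-orbital index ranges
so_occ <- function(so) seq_len(so$no)
so_virt <- function(so) so$no + seq_len(so$nv)

# slice <pq||rs> into a named block, e.g. so_block(so, "oovv")
so_block <- function(so, blk) {
  idx <- lapply(strsplit(blk, "")[[1]], function(ch)
    if (ch == "o") so_occ(so) else so_virt(so))
  so$aso[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
}
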