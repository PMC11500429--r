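#' Seeded synthetic closed-shell Hamiltonian
#'
#' Generates a valid closed-shell MO-basis Hamiltonian for testing: the
#' two-electron tensor is built as G G^T over compound pair indices from
#' symmetric random generators (hence positive semidefinite with exact 8-fold
#' permutational symmetry), and the one-electron matrix is chosen so that the
#' closed-shell Fock matrix is exactly diagonal with a prescribed ascending
#' spectrum - i.e. the reference determinant is canonical by construction.
#' The interaction strength is a dial: at \code{interaction_scale = 0} the
#' Hamiltonian is pure Fock and all correlation amplitudes vanish; the default
#' 0.1 yields well-behaved CCSD/CC3 fixtures with a clear HOMO-LUMO gap.
#'
#' @param n_occ,n_virt spatial occupied/virtual counts.
#' @param seed integer seed; the output is bit-reproducible for a fixed seed.
#' @param interaction_scale dimensionless scale of the fluctuation potential.
#' @param gap HOMO-LUMO gap in hartree.
#' @param n_aux_target number of symmetric generators for the ERI tensor
#'   (defaults to \code{n_mo + 2}); the ERI pair matrix has rank at most this.
#' @return list with \code{spaces} and \code{ints}.
#' @export
synth_hamiltonian <- function(n_occ, n_virt, seed = 1L,
                              interaction_scale = 0.1, gap = 1.0,
                              n_aux_target = NULL) {
  O <- as.integer(n_occ); V <- as.integer(n_virt); n <- O + V
  if (is.null(n_aux_target)) n_aux_target <- n + 2L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # ERIs: (pq|rs) = sum_m A^m_pq A^m_rs with symmetric A^m -> PSD + 8-fold
  g <- array(0, dim = c(n, n, n, n))
  for (m in seq_len(n_aux_target)) {
    A <- matrix(stats::rnorm(n * n), n, n)
    A <- (A + t(A)) / 2
    # damp off-diagonal blocks slightly so the Fock-dominant regime is generic
    g <- g + outer(A, A)
  }
  g <- g * (interaction_scale / n_aux_target)
  g <- symmetrize8(g)
  # target canonical spectrum: ascending with the requested gap
  eps_occ <- sort(stats::runif(O, -2.5, -1.0 - gap / 2))
  eps_virt <- sort(stats::runif(V, -1.0 + gap / 2, 1.5))
  eps_occ <- eps_occ - (max(eps_occ) - (-1.0 - gap / 2))  # enforce gap >= gap
  eps <- c(eps_occ, eps_virt)
  # choose h so the closed-shell Fock is exactly diag(eps)
  occ <- seq_len(O)
  J <- apply(g[, , occ, occ, drop = FALSE], c(1, 2),
             function(m) sum(diag(as.matrix(m))))
  K <- matrix(0, n, n)
  for (i in occ) K <- K + g[, i, i, ]
  h <- diag(eps, n) - (2 * J - K)
  h <- (h + t(h)) / 2
  ints <- mo_integrals(h, g, n_electrons = 2L * O, e_core = 0)
  spaces <- orbital_spaces(O, V, eps_occ, eps_virt)
  list(spaces = spaces, ints = ints)
}

# save/restore global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Packaged fixture suite
#'
#' Three deterministic synthetic Hamiltonians used throughout the tests and
#' the acceptance checks: \code{"tiny"} (O=1, V=2, a two-electron system where
#' CCSD and EOM-CCSD are exact), \code{"small"} (O=2, V=3, the full-rank
#' equivalence fixture) and \code{"medium"} (O=3, V=5, the rank-scan fixture).
#'
#' @param name one of "tiny", "small", "medium".
#' @param seed base seed (fixture seeds are offsets from it).
#' @export
fixture_hamiltonian <- function(name = c("tiny", "small", "medium"), seed = 42L) {
  name <- match.arg(name)
  switch(name,
    tiny = synth_hamiltonian(1, 2, seed = seed + 1L, interaction_scale = 0.15),
    small = synth_hamiltonian(2, 3, seed = seed + 2L, interaction_scale = 0.12),
    medium = synth_hamiltonian(3, 5, seed = seed + 3L, interaction_scale = 0.10))
}
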