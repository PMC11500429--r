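#' Orbital space bookkeeping
#'
#' Describes the occupied/virtual partition of an active molecular-orbital
#' space for a closed-shell reference: O doubly occupied active orbitals with
#' energies \code{eps_occ}, V virtual orbitals with energies \code{eps_virt},
#' and the number of frozen-core orbitals excluded from correlation.
#' \code{n_mo} is the number of active molecular orbitals, O + V, excluding
#' frozen-core orbitals; it is the natural unit for the triple-excitation
#' subspace ranks.
#'
#' @param n_occ number of active occupied (spatial) orbitals, O >= 1.
#' @param n_virt number of virtual (spatial) orbitals, V >= 1.
#' @param eps_occ,eps_virt orbital energies in hartree, ascending per block.
#' @param n_frozen_core number of frozen-core orbitals already removed.
#' @return an object of class \code{orbital_spaces}.
#' @export
orbital_spaces <- function(n_occ, n_virt, eps_occ, eps_virt, n_frozen_core = 0L) {
  n_occ <- as.integer(n_occ); n_virt <- as.integer(n_virt)
  if (n_occ < 1L || n_virt < 1L) stop("need at least one occupied and one virtual orbital")
  if (length(eps_occ) != n_occ || length(eps_virt) != n_virt)
    stop("orbital energy vectors do not match the space dimensions")
  if (is.unsorted(eps_occ) || is.unsorted(eps_virt))
    stop("orbital energies must be ascending within each block")
  structure(list(n_occ = n_occ, n_virt = n_virt,
                 eps_occ = as.numeric(eps_occ), eps_virt = as.numeric(eps_virt),
                 n_frozen_core = as.integer(n_frozen_core),
                 n_mo = n_occ + n_virt),
            class = "orbital_spaces")
}

#' @export
print.orbital_spaces <- function(x, ...) {
  cat("orbital_spaces: O =", x$n_occ, " V =", x$n_virt,
      " N_MO =", x$n_mo, " frozen core =", x$n_frozen_core, "\n")
  cat("  HOMO-LUMO gap:", format(min(x$eps_virt) - max(x$eps_occ)), "hartree\n")
  invisible(x)
}

#' HOMO-LUMO gap of an orbital space
#' @param spaces an \code{orbital_spaces} object.
#' @export
homo_lumo_gap <- function(spaces) min(spaces$eps_virt) - max(spaces$eps_occ)

#' Freeze core orbitals
#'
#' Removes the \code{n_core} lowest-energy occupied orbitals from the
#' correlated space and folds their mean-field interaction into the one-body
#' operator and the core energy, so that a correlated calculation in the
#' reduced space is equivalent to constraining the core orbitals to remain
#' doubly occupied.
#'
#' @param spaces an \code{orbital_spaces} for the full (unfrozen) problem.
#' @param ints matching \code{mo_integrals}.
#' @param n_core number of core orbitals to freeze (0 leaves input unchanged).
#' @return list with elements \code{spaces} and \code{ints} for the active space.
#' @export
select_frozen_core <- function(spaces, ints, n_core) {
  n_core <- as.integer(n_core)
  if (n_core < 0L || n_core > spaces$n_occ - 1L)
    stop("n_core out of range: must leave at least one active occupied orbital")
  if (n_core == 0L)
    return(list(spaces = spaces, ints = ints))
  n <- spaces$n_mo
  core <- seq_len(n_core)          # lowest-energy occupied orbitals come first
  act <- setdiff(seq_len(n), core)
  h <- ints$h; g <- ints$g
  # mean-field potential of the frozen core on the active orbitals
  vJ <- apply(g[, , core, core, drop = FALSE], c(1, 2),
              function(m) sum(diag(as.matrix(m))))
  vK <- matrix(0, n, n)
  for (c0 in core) vK <- vK + g[, c0, c0, ]
  h_eff <- h + 2 * vJ - vK
  e_core <- 2 * sum(diag(h)[core])
  for (c1 in core) for (c2 in core)
    e_core <- e_core + 2 * g[c1, c1, c2, c2] - g[c1, c2, c2, c1]
  new_ints <- mo_integrals(h = h_eff[act, act, drop = FALSE],
                           g = g[act, act, act, act, drop = FALSE],
                           n_electrons = ints$n_electrons - 2L * n_core,
                           e_core = ints$e_core + e_core)
  new_spaces <- orbital_spaces(
    n_occ = spaces$n_occ - n_core, n_virt = spaces$n_virt,
    eps_occ = spaces$eps_occ[-core], eps_virt = spaces$eps_virt,
    n_frozen_core = spaces$n_frozen_core + n_core)
  list(spaces = new_spaces, ints = new_ints)
}
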