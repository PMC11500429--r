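#' Rank-scan driver
#'
#' Runs the RR-EOM-CC3 pipeline over a grid of triple-excitation subspace
#' sizes along the diagonal policy N_SVD = N_svd (unless \code{n_SVD_grid}
#' overrides it) and tabulates the excitation energy and its deviation from
#' the full-rank (N = O*V) reference, which is appended to the grid if
#' absent.
#'
#' @param ints,spaces Hamiltonian and spaces.
#' @param grid integer vector of ranks.
#' @param state target state index.
#' @param n_SVD_grid optional separate excited-state ranks (default: grid).
#' @param seed seed passed to the solvers.
#' @param ... further arguments to \code{\link{solve_rr_eom_cc3}}.
#' @return data.frame: \code{rank}, \code{omega} (hartree), \code{omega_ev},
#'   \code{abs_error} vs the full-rank omega (hartree).
#' @export
rank_scan <- function(ints, spaces, grid, state = 1L, n_SVD_grid = NULL,
                      seed = 1L, conv_energy = 1e-7, conv_residual = 1e-6,
                      ...) {
  nov <- spaces$n_occ * spaces$n_virt
  grid <- sort(unique(pmin(as.integer(grid), nov)))
  if (is.null(n_SVD_grid)) n_SVD_grid <- grid
  full_in_grid <- nov %in% grid
  ranks <- if (full_in_grid) grid else c(grid, nov)
  svds <- if (full_in_grid) n_SVD_grid else c(n_SVD_grid, nov)
  so <- spin_orbital_basis(ints, spaces)
  ccsd <- solve_ccsd(so)
  eom <- solve_eom_ccsd(ints, spaces, ccsd, n_roots = state,
                        conv_energy = conv_energy,
                        conv_residual = conv_residual)
  guess <- eom[[state]]
  omegas <- numeric(length(ranks))
  for (k in seq_along(ranks)) {
    ground <- solve_cc3_ground_rr(ints, spaces, ranks[k], seed = seed)
    rr <- solve_rr_eom_cc3(ints, spaces, ground, guess, svds[k],
                           conv_energy = conv_energy,
                           conv_residual = conv_residual, seed = seed, ...)
    omegas[k] <- rr$omega
  }
  full <- omegas[length(ranks)]
  out <- data.frame(rank = ranks, omega = omegas,
                    omega_ev = omegas * hartree_to_ev(),
                    abs_error = abs(omegas - full))
  if (!full_in_grid) out <- out[out$rank %in% grid | out$rank == nov, ]
  out
}
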