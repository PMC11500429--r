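# Ground-state CC3 (dense oracle and rank-reduced) and the EOM-CC3 solvers.
#
# Workflow of a rank-reduced run:
#   CCSD -> HOOI on the (T)-type ground guess -> RR-CC3 ground iterations
#   -> block-Davidson EOM-CCSD -> HOOI on the excited-state guess
#   -> omega-self-consistent single-root RR-EOM-CC3.
# The dense oracle solvers mirror each stage with explicitly constructed
# rank-6 triples for verification at desk scale.

# spatial blocks of singlet spin-orbital amplitudes
spat_c1 <- function(r1, O, V) r1[seq_len(O), seq_len(V), drop = FALSE]
spat_c2 <- function(r2, O, V)
  r2[seq_len(O), O + seq_len(O), seq_len(V), V + seq_len(V), drop = FALSE]

# pilot projector from the doubles amplitudes: leading left singular vectors
# of the pair unfolding, completed with a seeded random orthonormal basis
.doubles_pilot <- function(t2sp, rank, seed = 7L) {
  O <- dim(t2sp)[1]; V <- dim(t2sp)[3]; nov <- O * V
  M <- aperm(t2sp, c(1, 3, 2, 4)); dim(M) <- c(nov, nov)
  sv <- svd(M, nu = min(rank, nov), nv = 0)
  U <- sv$u
  if (ncol(U) < rank) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    U <- qr.Q(qr(cbind(U, matrix(stats::rnorm(nov * (rank - ncol(U))),
                                 nov, rank - ncol(U)))))
  }
  U[, seq_len(rank), drop = FALSE]
}

#' Ground-state CC3 with dense triples (oracle scale)
#'
#' Iterates the CCSD equations augmented with the triples contributions
#' evaluated from the explicitly constructed rank-6 T3 of the CC3
#' approximation.
#'
#' @param ints,spaces Hamiltonian and spaces.
#' @param conv_energy,conv_residual,max_iter solver controls.
#' @return list: \code{cc} (amplitudes), \code{t3} (dense triples),
#'   \code{dressed} (dense dressed integrals at convergence).
#' @export
solve_cc3_ground_dense <- function(ints, spaces, conv_energy = 1e-8,
                                   conv_residual = 1e-7, max_iter = 100L) {
  O <- spaces$n_occ; V <- spaces$n_virt
  .oracle_guard(O, V)
  so <- spin_orbital_basis(ints, spaces)
  extra <- function(t1, t2) {
    t1sp <- spat_c1(t1, O, V); t2sp <- spat_c2(t2, O, V)
    dd <- dress_dense(ints$h, ints$g, t1sp, O)
    gam <- dense_gamma(t2sp, dd$g, O, V)
    w3 <- solve_dense_r3(gam, spaces$eps_occ, spaces$eps_virt, omega = 0)
    sg <- dense_sigma_triples(w3, dd$g,
                              dd$fock[seq_len(O), O + seq_len(V), drop = FALSE],
                              O, V)
    list(r1 = singlet_r1_so(sg$s1), r2 = singlet_r2_so(sg$s2))
  }
  cc <- solve_ccsd(so, conv_energy = conv_energy,
                   conv_residual = conv_residual, max_iter = max_iter,
                   extra_rhs = extra)
  t1sp <- spat_c1(cc$t1, O, V); t2sp <- spat_c2(cc$t2, O, V)
  dd <- dress_dense(ints$h, ints$g, t1sp, O)
  gam <- dense_gamma(t2sp, dd$g, O, V)
  w3 <- solve_dense_r3(gam, spaces$eps_occ, spaces$eps_virt, omega = 0)
  list(cc = cc, t3 = w3, dressed = dd, so = so)
}

#' Rank-reduced ground-state CC3
#'
#' The triples projector U is computed by HOOI on the (T)-type guess
#' amplitudes of the converged CCSD doubles, canonicalized, and held fixed;
#' the CC3 iterations then solve for T1, T2 and the compressed core tensor
#' t_xyz.  With \code{n_svd = 0} the method reduces to CCSD; with
#' \code{n_svd = O*V} it is exactly equivalent to the dense CC3.
#'
#' @param ints,spaces Hamiltonian and spaces.
#' @param n_svd ground triples rank (absolute; see \code{\link{resolve_rank}}).
#' @param conv_energy,conv_residual,max_iter solver controls.
#' @param df optional precomputed \code{df_factors}.
#' @param chol_tol Cholesky threshold when \code{df} is not supplied.
#' @param hooi_max_iter,hooi_tol,laplace_tol,denominator_guard numerics.
#' @param seed seed for HOOI fallback initialization.
#' @return list: \code{cc}, \code{triples} (projector \code{u}, \code{core},
#'   \code{eps}), \code{df}, \code{hooi}.
#' @export
solve_cc3_ground_rr <- function(ints, spaces, n_svd, conv_energy = 1e-8,
                                conv_residual = 1e-7, max_iter = 100L,
                                df = NULL, chol_tol = 1e-8,
                                hooi_max_iter = 50L, hooi_tol = 1e-4,
                                laplace_tol = 1e-6, denominator_guard = 1e-6,
                                seed = 1L) {
  O <- spaces$n_occ; V <- spaces$n_virt; nov <- O * V
  so <- spin_orbital_basis(ints, spaces)
  if (is.null(df)) df <- cholesky_factorize(ints, tol = chol_tol)
  cc0 <- solve_ccsd(so, conv_energy = conv_energy,
                    conv_residual = conv_residual, max_iter = max_iter)
  if (n_svd == 0L)
    return(list(cc = cc0, triples = NULL, df = df, hooi = NULL, so = so))
  if (n_svd > nov) {
    warning("n_svd = ", n_svd, " exceeds O*V = ", nov, "; clipped")
    n_svd <- nov
  }
  t1sp <- spat_c1(cc0$t1, O, V); t2sp <- spat_c2(cc0$t2, O, V)
  dr0 <- dress_t1(df, ints$h, t1sp, O)
  prov <- pt_triples_provider(t2sp, dr0$b, spaces$eps_occ, spaces$eps_virt,
                              shift = 0, laplace_tol = laplace_tol)
  hooi <- hooi_decompose(prov, n_svd, nov,
                         init = .doubles_pilot(t2sp, n_svd, seed = seed),
                         max_iter = hooi_max_iter, tol = hooi_tol, seed = seed)
  can <- canonicalize_projector(hooi$v, spaces$eps_occ, spaces$eps_virt)
  u <- can$v; eps_x <- can$eps
  extra <- function(t1, t2) {
    t1sp <- spat_c1(t1, O, V); t2sp <- spat_c2(t2, O, V)
    drt <- dress_t1(df, ints$h, t1sp, O)
    Bp <- list(list(drt$b, drt$b))
    core <- compute_core(gamma_projected(t2sp, Bp, u, O, V), eps_x,
                         omega = 0, guard = denominator_guard)
    s1 <- sigma1_from_core(core, u, Bp, O, V)
    s2 <- sigma2_from_core(core, u, Bp,
                           drt$fock[seq_len(O), O + seq_len(V), drop = FALSE],
                           O, V)
    list(r1 = singlet_r1_so(s1), r2 = singlet_r2_so(s2))
  }
  cc <- solve_ccsd(so, conv_energy = conv_energy,
                   conv_residual = conv_residual, max_iter = max_iter,
                   extra_rhs = extra)
  t1f <- spat_c1(cc$t1, O, V); t2f <- spat_c2(cc$t2, O, V)
  drf <- dress_t1(df, ints$h, t1f, O)
  coref <- compute_core(gamma_projected(t2f, list(list(drf$b, drf$b)), u, O, V),
                        eps_x, omega = 0, guard = denominator_guard)
  list(cc = cc, triples = list(u = u, core = coref, eps = eps_x, rank = n_svd),
       df = df, hooi = hooi, dressed = drf, so = so)
}

# ---- EOM-CC3 ---------------------------------------------------------------

# omega-self-consistent single-root driver shared by the dense and RR paths
.eom_cc3_root <- function(sigma_at_omega, guess, env, conv_energy = 1e-5,
                          conv_residual = 1e-4, max_outer = 40L,
                          max_inner = 40L) {
  omega <- guess$omega
  v <- guess
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    sig_op <- function(x) sigma_at_omega(x, omega)
    roots <- suppressWarnings(
      block_davidson(sig_op, list(v), 1L, env,
                     conv_energy = conv_energy / 5,
                     conv_residual = conv_residual / 2,
                     max_iter = max_inner))
    root <- roots[[1]]
    ov <- abs(eom_dot(root, guess))
    if (ov < 0.5)
      warning("root flip: overlap with the guess state is ", format(ov))
    d_omega <- abs(root$omega - omega)
    trace <- c(trace, root$omega)
    omega <- root$omega
    v <- root
    if (d_omega <= 0.2 * conv_energy) { converged <- TRUE; break }
  }
  sg <- sigma_at_omega(v, omega)
  res <- max(amax(sg$s1 - omega * v$r1), amax(sg$s2 - omega * v$r2))
  if (res > conv_residual || !converged)
    warning("EOM-CC3 root not fully converged (residual ", format(res),
            ", omega trace length ", length(trace), ")")
  list(omega = omega, vector = eom_vector(v$r1, v$r2, omega), trace = trace,
       residual = res)
}

#' Dense canonical EOM-CC3 (oracle)
#'
#' Solves the omega-self-consistent single-root EOM-CC3 problem with
#' explicitly constructed rank-6 triples at every sigma build.
#'
#' @param ints,spaces Hamiltonian and spaces.
#' @param ground result of \code{\link{solve_cc3_ground_dense}}.
#' @param guess \code{eom_vector} from EOM-CCSD.
#' @param conv_energy,conv_residual Davidson thresholds.
#' @export
solve_dense_eom_cc3 <- function(ints, spaces, ground, guess,
                                conv_energy = 1e-5, conv_residual = 1e-4) {
  O <- spaces$n_occ; V <- spaces$n_virt
  .oracle_guard(O, V)
  env <- eom_env(ints, spaces, ground$cc)
  dd <- ground$dressed
  Fov <- dd$fock[seq_len(O), O + seq_len(V), drop = FALSE]
  t2sp <- spat_c2(ground$cc$t2, O, V)
  sigma_at_omega <- function(vct, omega) {
    base <- sigma_eom_ccsd(env, vct$r1, vct$r2)
    r1sp <- spat_c1(vct$r1, O, V); r2sp <- spat_c2(vct$r2, O, V)
    dp <- dress_dense_derivative(dd$h, dd$g, r1sp, O)
    gam <- dense_gamma(r2sp, dd$g, O, V) + dense_gamma(t2sp, dp$g, O, V)
    r3 <- solve_dense_r3(gam, spaces$eps_occ, spaces$eps_virt, omega = omega)
    sg <- dense_sigma_triples(r3, dd$g, Fov, O, V)
    sgT <- dense_sigma_triples(ground$t3, dp$g,
                               dp$fock[seq_len(O), O + seq_len(V), drop = FALSE],
                               O, V)
    list(s1 = base$s1 + singlet_r1_so(sg$s1),
         s2 = base$s2 + singlet_r2_so(sg$s2 + sgT$s2))
  }
  .eom_cc3_root(sigma_at_omega, guess, env,
                conv_energy = conv_energy, conv_residual = conv_residual)
}

#' Rank-reduced EOM-CC3 for one state
#'
#' The excited-state projector V is computed once by HOOI on the guess
#' amplitudes built from the EOM-CCSD state (doubles R2 and excitation energy
#' omega-CCSD), canonicalized and held fixed; the compressed core tensor
#' r_XYZ is recomputed with the current omega in every sigma build, so the
#' folded triples are omega-self-consistent.
#'
#' @param ints,spaces Hamiltonian and spaces.
#' @param ground result of \code{\link{solve_cc3_ground_rr}} (with triples).
#' @param guess \code{eom_vector} from EOM-CCSD (block Davidson stage).
#' @param n_SVD excited triples rank.
#' @param conv_energy,conv_residual Davidson thresholds (hartree / residual).
#' @param hooi_max_iter,hooi_tol,laplace_tol,denominator_guard numerics.
#' @param warm_start start the excited HOOI from the ground projector
#'   (default FALSE: cold start from the guess doubles pilot).
#' @param seed HOOI fallback seed.
#' @return list: \code{omega} (hartree), \code{vector}, \code{triples}
#'   (projector \code{v}, \code{eps}, \code{rank}), \code{trace}.
#' @export
solve_rr_eom_cc3 <- function(ints, spaces, ground, guess, n_SVD,
                             conv_energy = 1e-5, conv_residual = 1e-4,
                             hooi_max_iter = 50L, hooi_tol = 1e-4,
                             laplace_tol = 1e-6, denominator_guard = 1e-6,
                             warm_start = FALSE, seed = 1L) {
  O <- spaces$n_occ; V <- spaces$n_virt; nov <- O * V
  env <- eom_env(ints, spaces, ground$cc)
  if (n_SVD == 0L || is.null(ground$triples)) {
    # empty triple-excitation subspaces: EOM-CCSD
    sigma_at_omega <- function(vct, omega) sigma_eom_ccsd(env, vct$r1, vct$r2)
    out <- .eom_cc3_root(sigma_at_omega, guess, env,
                         conv_energy = conv_energy,
                         conv_residual = conv_residual)
    return(c(out, list(triples = NULL)))
  }
  if (n_SVD > nov) {
    warning("n_SVD = ", n_SVD, " exceeds O*V = ", nov, "; clipped")
    n_SVD <- nov
  }
  drf <- ground$dressed
  r2sp_guess <- spat_c2(guess$r2, O, V)
  prov <- pt_triples_provider(r2sp_guess, drf$b, spaces$eps_occ,
                              spaces$eps_virt, shift = guess$omega,
                              laplace_tol = laplace_tol)
  init <- if (warm_start && !is.null(ground$triples) &&
              ncol(ground$triples$u) >= n_SVD)
    ground$triples$u[, seq_len(n_SVD), drop = FALSE]
  else .doubles_pilot(r2sp_guess, n_SVD, seed = seed)
  hooi <- hooi_decompose(prov, n_SVD, nov, init = init,
                         max_iter = hooi_max_iter, tol = hooi_tol, seed = seed)
  can <- canonicalize_projector(hooi$v, spaces$eps_occ, spaces$eps_virt)
  Vp <- can$v; eps_X <- can$eps
  t2sp <- spat_c2(ground$cc$t2, O, V)
  Fov <- drf$fock[seq_len(O), O + seq_len(V), drop = FALSE]
  Bp <- list(list(drf$b, drf$b))
  gt <- ground$triples
  sigma_at_omega <- function(vct, omega) {
    base <- sigma_eom_ccsd(env, vct$r1, vct$r2)
    r1sp <- spat_c1(vct$r1, O, V); r2sp <- spat_c2(vct$r2, O, V)
    ddv <- dress_derivative(drf, ints$h, r1sp)
    Bpd <- list(list(drf$b, ddv$b), list(ddv$b, drf$b))
    gh <- gamma_projected(r2sp, Bp, Vp, O, V) +
      gamma_projected(t2sp, Bpd, Vp, O, V)
    core_r <- compute_core(gh, eps_X, omega = omega,
                           guard = denominator_guard)
    s1 <- sigma1_from_core(core_r, Vp, Bp, O, V)
    s2 <- sigma2_from_core(core_r, Vp, Bp, Fov, O, V)
    s2 <- s2 + sigma2_from_core(gt$core, gt$u, Bpd,
                                ddv$fock[seq_len(O), O + seq_len(V),
                                         drop = FALSE], O, V)
    list(s1 = base$s1 + singlet_r1_so(s1),
         s2 = base$s2 + singlet_r2_so(s2))
  }
  out <- .eom_cc3_root(sigma_at_omega, guess, env,
                       conv_energy = conv_energy,
                       conv_residual = conv_residual)
  c(out, list(triples = list(v = Vp, eps = eps_X, rank = n_SVD),
              hooi = hooi))
}

#' Resolve a rank specification
#'
#' Rank inputs are accepted as absolute integers or as multiples of the
#' number of active molecular orbitals (e.g. \code{"1.0*nmo"}); the
#' recommended default policy is the diagonal N_SVD = N_svd = 1.0 N_MO.
#'
#' @param x integer, numeric, or string \code{"<factor>*nmo"}.
#' @param spaces \code{orbital_spaces}.
#' @export
resolve_rank <- function(x, spaces) {
  if (is.character(x)) {
    if (grepl("^[0-9]+$", trimws(x))) return(as.integer(trimws(x)))
    m <- regmatches(x, regexec("^([0-9.]+)\\s*\\*\\s*nmo$", tolower(x)))[[1]]
    if (length(m) < 2L) stop("cannot parse rank specification '", x, "'")
    return(as.integer(round(as.numeric(m[2]) * spaces$n_mo)))
  }
  as.integer(round(x))
}

#' Full RR-EOM-CC3 pipeline
#'
#' Runs CCSD, the ground HOOI and RR-CC3, block-Davidson EOM-CCSD, the
#' excited HOOI and the single-root RR-EOM-CC3 for the requested state.
#'
#' @param ints,spaces Hamiltonian and spaces (e.g. from
#'   \code{\link{read_fcidump}} or \code{\link{synth_hamiltonian}}).
#' @param state index of the target singlet excited state (1 = lowest).
#' @param n_svd,n_SVD triples ranks (default \code{"1.0*nmo"} each).
#' @param frozen_core number of core orbitals to freeze before correlation.
#' @param conv_energy,conv_residual Davidson thresholds.
#' @param gs_conv_energy,gs_conv_residual ground-state thresholds.
#' @param seed seed for stochastic fallbacks.
#' @param ... further arguments to \code{\link{solve_rr_eom_cc3}}.
#' @return list with omegas (hartree and eV), \code{percent_r2}, stage
#'   results and convergence traces.
#' @export
run_rr_eom_cc3 <- function(ints, spaces, state = 1L, n_svd = "1.0*nmo",
                           n_SVD = "1.0*nmo", frozen_core = 0L,
                           conv_energy = 1e-5, conv_residual = 1e-4,
                           gs_conv_energy = 1e-8, gs_conv_residual = 1e-7,
                           seed = 1L, ...) {
  if (frozen_core > 0L) {
    fc <- select_frozen_core(spaces, ints, frozen_core)
    ints <- fc$ints; spaces <- fc$spaces
  }
  n_svd <- min(resolve_rank(n_svd, spaces), spaces$n_occ * spaces$n_virt)
  n_SVD <- min(resolve_rank(n_SVD, spaces), spaces$n_occ * spaces$n_virt)
  ground <- solve_cc3_ground_rr(ints, spaces, n_svd,
                                conv_energy = gs_conv_energy,
                                conv_residual = gs_conv_residual, seed = seed)
  so <- ground$so
  ccsd <- solve_ccsd(so, conv_energy = gs_conv_energy,
                     conv_residual = gs_conv_residual)
  eom <- solve_eom_ccsd(ints, spaces, ccsd, n_roots = state,
                        conv_energy = conv_energy,
                        conv_residual = conv_residual)
  guess <- eom[[state]]
  root <- solve_rr_eom_cc3(ints, spaces, ground, guess, n_SVD,
                           conv_energy = conv_energy,
                           conv_residual = conv_residual, seed = seed, ...)
  list(omega = root$omega, omega_ev = root$omega * hartree_to_ev(),
       omega_ccsd = guess$omega, omega_ccsd_ev = guess$omega * hartree_to_ev(),
       percent_r2 = percent_r2(root$vector),
       percent_r2_ccsd = percent_r2(guess),
       e_hf = hf_energy(ints, spaces$n_occ), e_corr = ground$cc$e_corr,
       n_svd = n_svd, n_SVD = n_SVD, state = state,
       vector = root$vector, ground = ground, eom_ccsd = eom,
       trace = root$trace, residual = root$residual)
}
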