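# Closed-shell CCSD in the spin-orbital representation.
#
# Standard spin-orbital CCSD with one- and two-body intermediates and DIIS
# acceleration.  The reference is canonical (diagonal Fock), so occupied-
# virtual Fock elements vanish and amplitude updates divide by orbital-energy
# differences.  The solver is verified against full CI on two-electron
# systems and against determinant-space residuals of e^(-T) H e^(T).

#' CCSD amplitudes
#' @param t1 singles \code{[i,a]} (spin orbitals).
#' @param t2 doubles \code{[i,j,a,b]}, antisymmetric in (i,j) and (a,b).
#' @param e_corr correlation energy in hartree.
#' @param converged,iters solver diagnostics.
#' @export
ccsd_amplitudes <- function(t1, t2, e_corr, converged = TRUE, iters = NA) {
  structure(list(t1 = t1, t2 = t2, e_corr = e_corr,
                 converged = converged, iters = iters),
            class = "ccsd_amplitudes")
}

#' @export
print.ccsd_amplitudes <- function(x, ...) {
  cat("ccsd_amplitudes: e_corr =", format(x$e_corr), "hartree;",
      "max |t1| =", format(amax(x$t1)), " max |t2| =", format(amax(x$t2)),
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# antisymmetrizers over [i,j,a,b]
.Pij <- function(x) x - tperm("ijab->jiab", x)
.Pab <- function(x) x - tperm("ijab->ijba", x)

# orbital-energy denominators
.denoms <- function(so) {
  eo <- so$eps[so_occ(so)]; ev <- so$eps[so_virt(so)]
  D1 <- outer(eo, ev, "-")
  D2 <- outer(outer(eo, eo, "+"), outer(ev, ev, "+"), "-")
  list(D1 = D1, D2 = D2, eo = eo, ev = ev)
}

# CCSD residual right-hand sides such that the fixed point satisfies
# t1 = r1 / D1, t2 = r2 / D2 (canonical reference).
.ccsd_rhs <- function(so, t1, t2) {
  oovv <- so_block(so, "oovv"); ooov <- so_block(so, "ooov")
  oooo <- so_block(so, "oooo"); vvvv <- so_block(so, "vvvv")
  ovvv <- so_block(so, "ovvv"); ovov <- so_block(so, "ovov")
  vovv <- so_block(so, "vovv"); oovo <- so_block(so, "oovo")
  ovvo <- so_block(so, "ovvo"); vvvo <- so_block(so, "vvvo")
  ovoo <- so_block(so, "ovoo")

  t1t1 <- ein2("ia,jb->ijab", t1, t1)
  t1t1 <- t1t1 - tperm("ijab->ijba", t1t1)
  taut <- t2 + 0.5 * t1t1
  tau <- t2 + t1t1

  Fae <- ein2("mf,mafe->ae", t1, ovvv) -
    0.5 * ein2("mnaf,mnef->ae", taut, oovv)
  Fmi <- ein2("ne,mnie->mi", t1, ooov) +
    0.5 * ein2("inef,mnef->mi", taut, oovv)
  Fme <- ein2("nf,mnef->me", t1, oovv)

  Wtmp <- ein2("je,mnie->mnij", t1, ooov)
  Wmnij <- oooo + (Wtmp - tperm("mnij->mnji", Wtmp)) +
    0.25 * ein2("ijef,mnef->mnij", tau, oovv)
  Wtmp <- ein2("mb,amef->abef", t1, vovv)
  Wabef <- vvvv - (Wtmp - tperm("abef->baef", Wtmp)) +
    0.25 * ein2("mnab,mnef->abef", tau, oovv)
  Xjnfb <- 0.5 * t2 + ein2("jf,nb->jnfb", t1, t1)   # [j,n,f,b]
  Wmbej <- ovvo + ein2("jf,mbef->mbej", t1, ovvv) -
    ein2("nb,mnej->mbej", t1, oovo) -
    ein2("jnfb,mnef->mbej", Xjnfb, oovv)

  r1 <- ein2("ie,ae->ia", t1, Fae) -
    ein2("ma,mi->ia", t1, Fmi) +
    ein2("imae,me->ia", t2, Fme) -
    ein2("nf,naif->ia", t1, ovov) -
    0.5 * ein2("imef,maef->ia", t2, ovvv) -
    0.5 * ein2("mnae,nmei->ia", t2, oovo)

  FbeH <- Fae - 0.5 * ein2("mb,me->be", t1, Fme)
  FmjH <- Fmi + 0.5 * ein2("je,me->mj", t1, Fme)
  ring <- ein2("imae,mbej->ijab", t2, Wmbej) -
    ein2("iema,mbej->ijab", ein2("ie,ma->iema", t1, t1), ovvo)
  r2 <- oovv +
    .Pab(ein2("ijae,be->ijab", t2, FbeH)) -
    .Pij(ein2("imab,mj->ijab", t2, FmjH)) +
    0.5 * ein2("mnab,mnij->ijab", tau, Wmnij) +
    0.5 * ein2("ijef,abef->ijab", tau, Wabef) +
    .Pij(.Pab(ring)) +
    .Pij(ein2("ie,abej->ijab", t1, vvvo)) -
    .Pab(ein2("ma,mbij->ijab", t1, ovoo))
  list(r1 = r1, r2 = r2, oovv = oovv)
}

# CCSD correlation energy for given amplitudes
.cc_energy <- function(oovv, t1, t2) {
  0.25 * sum(oovv * t2) + 0.5 * sum(oovv * ein2("ia,jb->ijab", t1, t1))
}

# simple DIIS extrapolation over flattened amplitude vectors
.diis_new <- function(hist, depth = 6L) {
  hist <- utils::tail(hist, depth)
  n <- length(hist)
  if (n < 2L) return(hist[[n]]$x)
  B <- matrix(0, n + 1L, n + 1L)
  for (i in seq_len(n)) for (j in seq_len(n))
    B[i, j] <- sum(hist[[i]]$e * hist[[j]]$e)
  B[n + 1L, seq_len(n)] <- -1; B[seq_len(n), n + 1L] <- -1
  rhs <- c(rep(0, n), -1)
  c_sol <- tryCatch(solve(B, rhs), error = function(e) NULL)
  if (is.null(c_sol)) return(hist[[n]]$x)
  x <- 0
  for (i in seq_len(n)) x <- x + c_sol[i] * hist[[i]]$x
  x
}

#' Solve closed-shell CCSD
#'
#' @param so spin-orbital basis from \code{\link{spin_orbital_basis}}.
#' @param conv_energy,conv_residual convergence thresholds (hartree /
#'   max residual amplitude); defaults are tight so amplitude noise does not
#'   pollute downstream excitation energies.
#' @param max_iter iteration cap; @param diis_depth DIIS subspace depth.
#' @param extra_rhs optional function(t1, t2) returning additional residual
#'   contributions \code{list(r1, r2)} (used by the CC3 ground-state solvers
#'   to fold in triples).
#' @return \code{ccsd_amplitudes}.
#' @export
solve_ccsd <- function(so, conv_energy = 1e-8, conv_residual = 1e-7,
                       max_iter = 100L, diis_depth = 6L, extra_rhs = NULL) {
  d <- .denoms(so)
  t1 <- array(0, dim = c(so$no, so$nv))
  t2 <- so_block(so, "oovv") / d$D2
  e_old <- Inf; hist <- list()
  for (it in seq_len(max_iter)) {
    rhs <- .ccsd_rhs(so, t1, t2)
    if (!is.null(extra_rhs)) {
      ex <- extra_rhs(t1, t2)
      rhs$r1 <- rhs$r1 + ex$r1
      rhs$r2 <- rhs$r2 + ex$r2
    }
    t1n <- rhs$r1 / d$D1
    t2n <- rhs$r2 / d$D2
    res <- max(amax(t1n - t1), amax(t2n - t2))
    x <- c(as.numeric(t1n), as.numeric(t2n))
    e <- c(as.numeric(t1n - t1), as.numeric(t2n - t2))
    hist[[length(hist) + 1L]] <- list(x = x, e = e)
    x <- .diis_new(hist, diis_depth)
    t1 <- array(x[seq_along(t1)], dim = dim(t1))
    t2 <- array(x[-seq_along(t1)], dim = dim(t2))
    t2 <- (t2 - tperm("ijab->jiab", t2) - tperm("ijab->ijba", t2) +
             tperm("ijab->jiba", t2)) / 4     # keep exact antisymmetry
    e_new <- .cc_energy(rhs$oovv, t1, t2)
    de <- abs(e_new - e_old); e_old <- e_new
    if (res <= conv_residual && de <= conv_energy)
      return(ccsd_amplitudes(t1, t2, e_new, converged = TRUE, iters = it))
  }
  warning("CCSD did not converge in ", max_iter,
          " iterations (residual ", format(res), ")")
  ccsd_amplitudes(t1, t2, e_old, converged = FALSE, iters = max_iter)
}
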