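# EOM-CCSD: sigma vectors and the block-Davidson eigensolver.
#
# The similarity-transformed Hamiltonian is handled in the T1-dressed
# formulation: with A~ = e^(-T1) A e^(T1) all explicit T1 terms disappear and
# the sigma vector decomposes into commutator brackets
#   s1 = <u1| [H~,R1] + [H~,R2] + [[H~,T2],R1] |0>
#   s2 = <u2| [H~,R1] + [H~,R2] + [[H~,T2],R1] + [[H~,T2],R2] |0>
# The R1 brackets use the identity [[H~,T2],R1] = [[H~,R1],T2], where
# [H~,R1] is the directional derivative of the dressing - a one-index
# replacement of the dressed integrals by r1 - so the same contraction code
# serves both the T2-linear and the derivative terms.  Every bracket is
# verified against determinant-space commutator matrices in the tests.

# ---- spin-orbital dressing --------------------------------------------------

# expand a spatial chemist Hamiltonian into spin-orbital chemist arrays
.spin_chem <- function(h, g, O, V) {
  n <- O + V
  spat <- c(seq_len(O), seq_len(O), O + seq_len(V), O + seq_len(V))
  spin <- c(rep(1L, O), rep(-1L, O), rep(1L, V), rep(-1L, V))
  same <- outer(spin, spin, "==") * 1.0
  list(h = h[spat, spat] * same,
       g = g[spat, spat, spat, spat] * outer(same, same),
       spat = spat, spin = spin, no = 2L * O, nv = 2L * V)
}

# dressing transformation matrices in spin-orbital space
.dress_mats_so <- function(t1so, no, nv) {
  n <- no + nv
  Tm <- matrix(0, n, n)
  Tm[no + seq_len(nv), seq_len(no)] <- t(t1so)
  list(Lc = diag(n) - Tm, La = diag(n) + t(Tm))
}

# transform all four chemist indices: creation slots (1,3) with Lc,
# annihilation slots (2,4) with La; every transform acts from the left.
.dress_g4 <- function(g, Lc, La) {
  g <- ein2("Pp,pqrs->Pqrs", Lc, g)
  g <- ein2("Qq,pqrs->pQrs", La, g)
  g <- ein2("Rr,pqrs->pqRs", Lc, g)
  ein2("Ss,pqrs->pqrS", La, g)
}

# spin-orbital mean-field completion: F_pq = h_pq + sum_m <pm||qm>
.fock_so <- function(h, g, no) {
  occ <- seq_len(no)
  J <- apply(g[, , occ, occ, drop = FALSE], c(1, 2),
             function(m) sum(diag(as.matrix(m))))
  K <- matrix(0, nrow(h), nrow(h))
  for (m in occ) K <- K + g[, m, m, ]
  h + J - K
}

# antisymmetrize chemist -> physicist <pq||rs>
.antisym_so <- function(g) aperm(g, c(1, 3, 2, 4)) - aperm(g, c(1, 3, 4, 2))

#' EOM-CCSD working environment
#'
#' Precomputes the T1-dressed spin-orbital integrals, dressed Fock matrix and
#' the pieces needed for the per-sigma derivative dressing.
#'
#' @param ints \code{mo_integrals}; @param spaces \code{orbital_spaces};
#' @param cc converged \code{ccsd_amplitudes} (spin-orbital; for EOM-CC3 pass
#'   the CC3 ground amplitudes).
#' @export
eom_env <- function(ints, spaces, cc) {
  O <- spaces$n_occ; V <- spaces$n_virt
  sc <- .spin_chem(ints$h, ints$g, O, V)
  M <- .dress_mats_so(cc$t1, sc$no, sc$nv)
  gd <- .dress_g4(sc$g, M$Lc, M$La)
  hd <- M$Lc %*% sc$h %*% t(M$La)
  Fd <- .fock_so(hd, gd, sc$no)
  W <- .antisym_so(gd)
  list(no = sc$no, nv = sc$nv, O = O, V = V,
       gd = gd, hd = hd, Fd = Fd, W = W, t2 = cc$t2, t1 = cc$t1,
       eo = rep(spaces$eps_occ, 2), ev = rep(spaces$eps_virt, 2))
}

# slice <pq||rs> blocks of a spin-orbital antisym array
.wblk <- function(W, no, nv, blk) {
  idx <- lapply(strsplit(blk, "")[[1]], function(ch)
    if (ch == "o") seq_len(no) else no + seq_len(nv))
  W[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
}

# derivative dressing in direction r1 (spin-orbital): returns the one-body
# and antisymmetrized two-body coefficients of [H~, R1]
.deriv_dress_so <- function(env, r1so) {
  n <- env$no + env$nv
  Rm <- matrix(0, n, n)
  Rm[env$no + seq_len(env$nv), seq_len(env$no)] <- t(r1so)
  dLc <- -Rm; dLa <- t(Rm)
  gp <- ein2("Pp,pqrs->Pqrs", dLc, env$gd) +
    ein2("Qq,pqrs->pQrs", dLa, env$gd) +
    ein2("Rr,pqrs->pqRs", dLc, env$gd) +
    ein2("Ss,pqrs->pqrS", dLa, env$gd)
  hp <- dLc %*% env$hd + env$hd %*% t(dLa)
  Fp <- .fock_so(hp, gp, env$no)
  list(W = .antisym_so(gp), F = Fp)
}

# ---- sigma vector ----------------------------------------------------------

# generic singles projection <u1|[O,d2]|0> for a one+two-body operator with
# Fock-like matrix Fm and antisym integrals W, contracted with doubles d2
.sig1_from_doubles <- function(Fm, W, d2, no, nv) {
  ov <- Fm[seq_len(no), no + seq_len(nv), drop = FALSE]
  ein2("me,imae->ia", ov, d2) +
    0.5 * ein2("amef,imef->ia", .wblk(W, no, nv, "vovv"), d2) -
    0.5 * ein2("mnie,mnae->ia", .wblk(W, no, nv, "ooov"), d2)
}

# generic doubles projection <u2|[O,d2]|0>
.sig2_from_doubles <- function(Fm, W, d2, no, nv) {
  o <- seq_len(no); v <- no + seq_len(nv)
  .Pab(ein2("be,ijae->ijab", Fm[v, v, drop = FALSE], d2)) -
    .Pij(ein2("mj,imab->ijab", Fm[o, o, drop = FALSE], d2)) +
    0.5 * ein2("mnij,mnab->ijab", .wblk(W, no, nv, "oooo"), d2) +
    0.5 * ein2("abef,ijef->ijab", .wblk(W, no, nv, "vvvv"), d2) +
    .Pij(.Pab(ein2("mbej,imae->ijab", .wblk(W, no, nv, "ovvo"), d2)))
}

#' EOM-CCSD sigma vector
#'
#' Action of the similarity-transformed Hamiltonian (singles and doubles
#' blocks) on an excitation vector; linear in (r1, r2).
#'
#' @param env from \code{\link{eom_env}}.
#' @param r1 spin-orbital singles \code{[i,a]}; @param r2 antisymmetric
#'   doubles \code{[i,j,a,b]}.
#' @return list with \code{s1}, \code{s2}.
#' @export
sigma_eom_ccsd <- function(env, r1, r2) {
  no <- env$no; nv <- env$nv
  o <- seq_len(no); v <- no + seq_len(nv)
  W <- env$W; Fd <- env$Fd; t2 <- env$t2
  pr <- .deriv_dress_so(env, r1)
  Woovv <- .wblk(W, no, nv, "oovv")

  s1 <- ein2("ae,ie->ia", Fd[v, v, drop = FALSE], r1) -
    ein2("mi,ma->ia", Fd[o, o, drop = FALSE], r1) +
    ein2("amie,me->ia", .wblk(W, no, nv, "voov"), r1) +
    .sig1_from_doubles(Fd, W, r2, no, nv) +
    .sig1_from_doubles(pr$F, pr$W, t2, no, nv)

  s2 <- .Pij(ein2("abej,ie->ijab", .wblk(W, no, nv, "vvvo"), r1)) -
    .Pab(ein2("mbij,ma->ijab", .wblk(W, no, nv, "ovoo"), r1)) +
    .sig2_from_doubles(Fd, W, r2, no, nv) +
    .sig2_from_doubles(pr$F, pr$W, t2, no, nv)

  # [[W~,T2],R2] quadratic terms
  X <- ein2("ijef,mnef->ijmn", t2, Woovv)
  s2 <- s2 + 0.25 * ein2("ijmn,mnab->ijab", X, r2)
  Y <- ein2("mnab,mnef->efab", t2, Woovv)
  s2 <- s2 + 0.25 * ein2("efab,ijef->ijab", Y, r2)
  Z <- ein2("mnef,jnfb->mejb", Woovv, t2)
  s2 <- s2 - .Pij(.Pab(ein2("imae,mejb->ijab", r2, Z)))
  dFv <- -0.5 * ein2("mnbf,mnef->be", t2, Woovv)
  s2 <- s2 + .Pab(ein2("be,ijae->ijab", dFv, r2))
  dFo <- 0.5 * ein2("jnef,mnef->mj", t2, Woovv)
  s2 <- s2 - .Pij(ein2("mj,imab->ijab", dFo, r2))
  Zv <- -0.5 * ein2("mnbf,mnef->be", r2, Woovv)
  s2 <- s2 + .Pab(ein2("be,ijae->ijab", Zv, t2))
  Zo <- 0.5 * ein2("jnef,mnef->mj", r2, Woovv)
  s2 <- s2 - .Pij(ein2("mj,imab->ijab", Zo, t2))

  list(s1 = s1, s2 = s2)
}

# ---- EOM vectors -----------------------------------------------------------

# inner product consistent with unique-excitation counting
eom_dot <- function(x, y) sum(x$r1 * y$r1) + 0.25 * sum(x$r2 * y$r2)
eom_norm <- function(x) sqrt(eom_dot(x, x))
eom_axpy <- function(a, x, y) list(r1 = a * x$r1 + y$r1, r2 = a * x$r2 + y$r2)
eom_scale <- function(a, x) list(r1 = a * x$r1, r2 = a * x$r2)

#' EOM excitation vector
#' @param r1,r2 spin-orbital amplitudes; @param omega excitation energy
#'   (hartree).
#' @export
eom_vector <- function(r1, r2, omega = NA_real_) {
  v <- list(r1 = r1, r2 = r2, omega = omega)
  class(v) <- "eom_vector"
  v
}

#' @export
print.eom_vector <- function(x, ...) {
  cat("eom_vector: omega =", format(x$omega), "hartree (",
      format(x$omega * hartree_to_ev()), "eV ), %R2 =",
      format(percent_r2(x), digits = 4), "\n")
  invisible(x)
}

#' Hartree to electronvolt conversion factor
#' @export
hartree_to_ev <- function() 27.211386245988

#' Percentage doubles character of an EOM vector
#'
#' 100 times the squared norm of the doubles block under unit normalization
#' (counting each unique excitation once); renormalizes with a warning if the
#' vector is not normalized.
#' @param vec \code{eom_vector}.
#' @export
percent_r2 <- function(vec) {
  n2 <- eom_dot(vec, vec)
  if (abs(n2 - 1) > 1e-8) {
    warning("unnormalized EOM vector (norm^2 = ", format(n2),
            "); renormalizing")
  }
  100 * 0.25 * sum(vec$r2^2) / n2
}

# expand a spatial singlet singles tensor into spin-orbital r1
singlet_r1_so <- function(c1) {
  O <- nrow(c1); V <- ncol(c1)
  r1 <- matrix(0, 2L * O, 2L * V)
  r1[seq_len(O), seq_len(V)] <- c1
  r1[O + seq_len(O), V + seq_len(V)] <- c1
  r1
}

# expand a spatial doubles tensor (any 4-tensor; only its pair-symmetric part
# enters) into antisymmetric spin-orbital r2 of the singlet operator
# (1/2) sum c2_ij^ab E_ai E_bj
singlet_r2_so <- function(c2) {
  O <- dim(c2)[1]; V <- dim(c2)[3]
  s <- (c2 + tperm("ijab->jiba", c2)) / 2
  r2 <- array(0, dim = c(2L * O, 2L * O, 2L * V, 2L * V))
  io <- seq_len(O); ib <- O + io; vo <- seq_len(V); vb <- V + vo
  sx <- s - tperm("ijab->ijba", s)
  r2[io, ib, vo, vb] <- s
  r2[ib, io, vb, vo] <- tperm("ijab->jiba", s)     # = s
  r2[io, ib, vb, vo] <- -tperm("ijab->ijba", s)
  r2[ib, io, vo, vb] <- -tperm("ijab->jiab", s)
  r2[io, io, vo, vo] <- sx
  r2[ib, ib, vb, vb] <- sx
  r2
}

#' Singlet CIS guesses for the Davidson solver
#'
#' Builds the singlet singles-singles block of the similarity-transformed
#' Hamiltonian by probing the sigma vector with unit singles, diagonalizes it
#' densely, and returns the lowest \code{n_roots} eigenvectors as singlet
#' \code{eom_vector}s with zero doubles.
#'
#' @param env from \code{\link{eom_env}}; @param n_roots count.
#' @export
cis_guess <- function(env, n_roots) {
  O <- env$O; V <- env$V
  nov <- O * V
  if (n_roots < 1L || n_roots > nov) stop("n_roots out of range [1, ", nov, "]")
  A <- matrix(0, nov, nov)
  z2 <- array(0, dim = c(env$no, env$no, env$nv, env$nv))
  for (col in seq_len(nov)) {
    c1 <- matrix(0, O, V); c1[col] <- 1
    sg <- sigma_eom_ccsd(env, singlet_r1_so(c1), z2)
    A[, col] <- as.numeric(sg$s1[seq_len(O), seq_len(V)])
  }
  ev <- eigen(A)
  if (max(abs(Im(ev$values))) > 1e-8)
    stop("complex eigenvalues in the CIS singles block")
  ord <- order(Re(ev$values))
  out <- vector("list", n_roots)
  for (k in seq_len(n_roots)) {
    c1 <- matrix(Re(ev$vectors[, ord[k]]), O, V)
    r1 <- singlet_r1_so(c1)
    r1 <- r1 / sqrt(sum(r1 * r1))
    out[[k]] <- eom_vector(r1, z2, omega = Re(ev$values[ord[k]]))
  }
  # re-orthonormalize within the guess block (defensive; eigenvectors of a
  # nonsymmetric block need not be orthogonal)
  for (k in seq_along(out)) {
    omega_k <- out[[k]]$omega
    for (l in seq_len(k - 1L))
      out[[k]] <- eom_axpy(-eom_dot(out[[l]], out[[k]]), out[[l]], out[[k]])
    out[[k]] <- eom_scale(1 / eom_norm(out[[k]]), out[[k]])
    out[[k]] <- eom_vector(out[[k]]$r1, out[[k]]$r2, omega = omega_k)
  }
  out
}

# ---- block Davidson --------------------------------------------------------

#' Block Davidson eigensolver for the (non-Hermitian) EOM problem
#'
#' Right eigenvectors only, oblique Rayleigh-Ritz in an orthonormal search
#' space, diagonal preconditioning by orbital-energy differences, restart on
#' subspace saturation, root homing by overlap with the previous iterate.
#'
#' @param sigma_op function(vec) -> list(s1, s2).
#' @param guesses list of \code{eom_vector} start vectors.
#' @param n_roots number of roots to converge.
#' @param env environment (for preconditioner energies).
#' @param conv_energy,conv_residual thresholds: change in omega (hartree) and
#'   max residual amplitude.
#' @param max_iter,max_subspace iteration and subspace caps.
#' @return list of converged \code{eom_vector}s sorted by omega.
#' @export
block_davidson <- function(sigma_op, guesses, n_roots, env,
                           conv_energy = 1e-5, conv_residual = 1e-4,
                           max_iter = 60L, max_subspace = NULL) {
  no <- env$no; nv <- env$nv
  if (is.null(max_subspace)) max_subspace <- max(8L * n_roots, 24L)
  D1 <- outer(env$eo, env$ev, "-")
  D2 <- outer(outer(env$eo, env$eo, "+"), outer(env$ev, env$ev, "+"), "-")
  basis <- list(); sig <- list()
  add_vec <- function(v) {
    for (b in basis) v <- eom_axpy(-eom_dot(b, v), b, v)
    for (b in basis) v <- eom_axpy(-eom_dot(b, v), b, v)  # reorthogonalize
    nrm <- eom_norm(v)
    if (nrm < 1e-7) return(FALSE)
    basis[[length(basis) + 1L]] <<- eom_scale(1 / nrm, v)
    s <- sigma_op(basis[[length(basis)]])
    sig[[length(sig) + 1L]] <<- list(r1 = s$s1, r2 = s$s2)
    TRUE
  }
  for (g in guesses) add_vec(g)
  # root homing: states are tracked by maximum overlap with these reference
  # vectors (initially the guesses), not by energy ordering - non-normal
  # subspace matrices can produce spurious low real Ritz values, and dark
  # states reorder during convergence
  targets <- guesses[seq_len(min(n_roots, length(guesses)))]
  omega_old <- rep(Inf, n_roots)
  for (it in seq_len(max_iter)) {
    nb <- length(basis)
    G <- matrix(0, nb, nb)
    for (i in seq_len(nb)) for (j in seq_len(nb))
      G[i, j] <- eom_dot(basis[[i]], sig[[j]])
    ev <- eigen(G)
    real_sel <- which(abs(Im(ev$values)) <= 1e-7 * max(1, abs(ev$values)))
    if (length(real_sel) < min(n_roots, nb))
      stop("complex eigenvalue pairs dominate the Davidson subspace; ",
           "non-real target roots are not supported")
    vals_all <- Re(ev$values)[real_sel]
    vecs_all <- Re(ev$vectors)[, real_sel, drop = FALSE]
    # assemble all real Ritz vectors once
    mk_ritz <- function(y) {
      rv <- list(r1 = basis[[1]]$r1 * 0, r2 = basis[[1]]$r2 * 0)
      sv <- list(r1 = rv$r1, r2 = rv$r2)
      for (i in seq_len(nb)) {
        rv <- eom_axpy(y[i], basis[[i]], rv)
        sv <- eom_axpy(y[i], sig[[i]], sv)
      }
      nrm <- eom_norm(rv)
      list(v = eom_scale(1 / nrm, rv), s = eom_scale(1 / nrm, sv))
    }
    cand <- lapply(seq_along(real_sel), function(k) mk_ritz(vecs_all[, k]))
    # greedy assignment of candidates to tracked targets by |overlap|
    nr <- min(n_roots, nb)
    while (length(targets) < nr)
      targets[[length(targets) + 1L]] <-
        guesses[[1L + (length(targets) %% length(guesses))]]
    ov <- matrix(0, length(cand), nr)
    for (c0 in seq_along(cand)) for (t0 in seq_len(nr))
      ov[c0, t0] <- abs(eom_dot(cand[[c0]]$v, targets[[t0]]))
    pick <- integer(nr)
    used <- logical(length(cand))
    for (t0 in order(-apply(ov, 2, max))) {
      sel <- which.max(ifelse(used, -1, ov[, t0]))
      pick[t0] <- sel; used[sel] <- TRUE
    }
    ritz <- vector("list", nr); res <- vector("list", nr)
    resmax <- numeric(nr)
    for (k in seq_len(nr)) {
      ck <- cand[[pick[k]]]
      vals_k <- vals_all[pick[k]]
      ritz[[k]] <- eom_vector(ck$v$r1, ck$v$r2, omega = vals_k)
      res[[k]] <- list(r1 = ck$s$r1 - vals_k * ck$v$r1,
                       r2 = ck$s$r2 - vals_k * ck$v$r2)
      resmax[k] <- max(amax(res[[k]]$r1), amax(res[[k]]$r2))
    }
    ord_k <- order(vapply(ritz, function(x) x$omega, numeric(1)))
    ritz <- ritz[ord_k]; res <- res[ord_k]; resmax <- resmax[ord_k]
    targets <- ritz
    vals <- vapply(ritz, function(x) x$omega, numeric(1))
    de <- abs(vals[seq_len(nr)] - omega_old[seq_len(nr)])
    omega_old[seq_len(nr)] <- vals[seq_len(nr)]
    if (nr == n_roots && all(resmax <= conv_residual) &&
        all(de <= conv_energy)) {
      return(ritz)
    }
    ritz_prev <- ritz
    added <- FALSE
    for (k in seq_len(nr)) {
      if (resmax[k] <= conv_residual && de[k] <= conv_energy) next
      prec1 <- res[[k]]$r1 / (vals[k] - D1 +
                                sign(vals[k] - D1 + 1e-12) * 1e-8)
      prec2 <- res[[k]]$r2 / (vals[k] - D2 +
                                sign(vals[k] - D2 + 1e-12) * 1e-8)
      if (add_vec(list(r1 = prec1, r2 = prec2))) added <- TRUE
    }
    if (!added || length(basis) > max_subspace) {
      # restart from current Ritz vectors
      basis <- list(); sig <- list()
      for (k in seq_len(nr)) add_vec(ritz[[k]])
      if (!added) next
    }
  }
  warning("block Davidson did not converge in ", max_iter, " iterations ",
          "(max residual ", format(max(resmax)), ")")
  ritz
}

#' Solve EOM-CCSD for the lowest singlet roots
#'
#' @param ints,spaces,cc Hamiltonian, spaces and ground-state amplitudes.
#' @param n_roots number of singlet roots.
#' @param conv_energy,conv_residual Davidson thresholds.
#' @param n_buffer extra buffer roots carried in the block (default 2).
#' @return list of normalized \code{eom_vector}s with omega in hartree.
#' @export
solve_eom_ccsd <- function(ints, spaces, cc, n_roots = 1L,
                           conv_energy = 1e-5, conv_residual = 1e-4,
                           n_buffer = 2L, max_iter = 60L) {
  env <- eom_env(ints, spaces, cc)
  nb <- min(n_roots + n_buffer, spaces$n_occ * spaces$n_virt)
  guesses <- cis_guess(env, nb)
  sigma_op <- function(v) sigma_eom_ccsd(env, v$r1, v$r2)
  roots <- block_davidson(sigma_op, guesses, nb, env,
                          conv_energy = conv_energy,
                          conv_residual = conv_residual, max_iter = max_iter)
  roots[seq_len(min(n_roots, length(roots)))]
}
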