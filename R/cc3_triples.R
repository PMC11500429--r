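# Triples machinery shared by the dense oracle and the rank-reduced path.
#
# Everything here works in the spatial-orbital pair representation: a triples
# tensor w[i,j,k,a,b,c] is symmetric under simultaneous permutations of its
# (occupied, virtual) index pairs, and the Tucker-3 format compresses it as
#   w = sum_XYZ core[X,Y,Z] V[ia,X] V[jb,Y] V[kc,Z]
# with a shared orthonormal projector V over the compound pair index.
#
# The triples equation (CC3 approximation) reads, in the canonical basis,
#   (omega - D_ijk^abc) R_ijk^abc = P3 gamma_ijk^abc,
# where P3 sums the six pair permutations, D = eps_abc - eps_ijk, and the
# generator is
#   gamma_ijk^abc = sum_d d2_ij^ad (bd|~ck) - sum_l d2_il^ab (lj|~ck),
# with d2 the doubles (T2 for the ground state with omega = 0, R2-CCSD for
# the excited-state guess, R2 in the EOM iterations), T1-dressed integrals,
# and - for the R1-dependent part of the excited-state equation - the
# directional-derivative-dressed integrals of [H~, R1] contracted with T2.
#
# The contributions of a triples tensor to the singles and doubles residuals
# are fixed linear functionals; the contraction tables below were derived by
# spin summation of the standard spin-orbital matrix elements through the
# exact spatial-to-spin amplitude map and verified to machine precision
# against determinant-space commutators.

.p3_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Pair-permutation symmetrizer P3
#'
#' Sums a rank-6 spatial triples tensor over the six simultaneous
#' permutations of its (occupied, virtual) index pairs.
#' @param w array \code{[i,j,k,a,b,c]}.
#' @export
symmetrize_p3 <- function(w) {
  out <- 0
  for (p in .p3_perms) out <- out + aperm(w, c(p, p + 3L))
  out
}

# sigma-from-triples contraction tables.  Each term: coefficient, integral
# ("F" = occupied-virtual Fock block F[m,e]; otherwise chemist labels of a
# dressed integral block (l1 l2|l3 l4)), and the six labels of w
# (occ1..3, virt1..3).  Output labels: "ia" (singles) / "ijab" (doubles,
# alpha-beta convention of the singlet fold).
.sigma1_terms <- list(
  list(c =  2.0, int = c("m","e","n","f"), w = c("i","m","n","a","e","f")),
  list(c = -1.0, int = c("m","e","n","f"), w = c("i","m","n","a","f","e")),
  list(c = -1.0, int = c("m","e","n","f"), w = c("i","m","n","e","a","f")),
  list(c =  0.5, int = c("m","e","n","f"), w = c("i","m","n","e","f","a")),
  list(c =  0.5, int = c("m","e","n","f"), w = c("i","m","n","f","a","e")),
  list(c = -1.0, int = c("m","e","n","f"), w = c("i","m","n","f","e","a")))

.sigma2_terms <- list(
  list(c =  2.0, int = "F",                w = c("i","j","m","a","b","e")),
  list(c = -1.0, int = "F",                w = c("i","j","m","a","e","b")),
  list(c = -1.0, int = "F",                w = c("i","j","m","e","b","a")),
  list(c =  2.0, int = c("a","e","m","f"), w = c("i","j","m","e","b","f")),
  list(c = -1.0, int = c("a","e","m","f"), w = c("i","j","m","e","f","b")),
  list(c = -1.0, int = c("a","e","m","f"), w = c("i","j","m","f","b","e")),
  list(c =  2.0, int = c("b","e","m","f"), w = c("i","j","m","a","e","f")),
  list(c = -1.0, int = c("b","e","m","f"), w = c("i","j","m","a","f","e")),
  list(c = -1.0, int = c("b","e","m","f"), w = c("i","j","m","f","e","a")),
  list(c =  0.5, int = c("m","e","n","i"), w = c("j","m","n","b","a","e")),
  list(c = -1.0, int = c("m","e","n","i"), w = c("j","m","n","b","e","a")),
  list(c =  0.5, int = c("m","e","n","i"), w = c("j","m","n","e","b","a")),
  list(c =  0.5, int = c("m","e","n","j"), w = c("i","m","n","a","b","e")),
  list(c = -1.0, int = c("m","e","n","j"), w = c("i","m","n","a","e","b")),
  list(c =  0.5, int = c("m","e","n","j"), w = c("i","m","n","e","a","b")),
  list(c = -1.0, int = c("m","i","n","e"), w = c("j","m","n","b","a","e")),
  list(c =  0.5, int = c("m","i","n","e"), w = c("j","m","n","b","e","a")),
  list(c =  0.5, int = c("m","i","n","e"), w = c("j","m","n","e","a","b")),
  list(c = -1.0, int = c("m","j","n","e"), w = c("i","m","n","a","b","e")),
  list(c =  0.5, int = c("m","j","n","e"), w = c("i","m","n","a","e","b")),
  list(c =  0.5, int = c("m","j","n","e"), w = c("i","m","n","e","b","a")))

.occ_labels <- c("i", "j", "k", "m", "n", "l")

# slice a dressed factor array B[n,n,Q] to the block demanded by two chemist
# labels (occ labels map to 1..O, virt labels to O+1..n)
.bslice <- function(B, l1, l2, O) {
  n <- dim(B)[1]
  ix <- function(l) if (l %in% .occ_labels) seq_len(O) else (O + 1L):n
  B[ix(l1), ix(l2), , drop = FALSE]
}

# triples denominator D_ijk^abc = eps_abc - eps_ijk
triples_denominator <- function(eps_o, eps_v) {
  O <- length(eps_o); V <- length(eps_v)
  Do <- outer(outer(eps_o, eps_o, "+"), eps_o, "+")
  Dv <- outer(outer(eps_v, eps_v, "+"), eps_v, "+")
  outer(-Do, Dv, "+")
}

# ---- factorized sigma contributions --------------------------------------

# operands for the Tucker representation of w attached to a term's w-labels
.tucker_ops <- function(term_w, core, Vun) {
  ops <- list(list(a = core, lab = "XYZ"))
  rk <- c("X", "Y", "Z")
  for (s in 1:3)
    ops[[length(ops) + 1L]] <- list(a = Vun,
                                    lab = paste0(term_w[s], term_w[s + 3L], rk[s]))
  ops
}

#' Factorized singles contribution of compressed triples
#'
#' Evaluates the triples term of the singles residual/sigma with the Tucker
#' representation of the triples and density-fitted dressed integrals; every
#' contraction step is a GEMM over at most five indices and no rank-6 tensor
#' is formed.
#'
#' @param core symmetric core tensor \code{[N,N,N]}.
#' @param Vp projector matrix \code{[O*V, N]} (pair index occ-fast).
#' @param Bpairs list of factor pairs \code{list(B1, B2)}; the integral is
#'   \code{sum_Q B1[p,q,Q] B2[r,s,Q]} summed over the listed pairs (one pair
#'   for plain dressed integrals, two for derivative dressing).
#' @param O,V active space sizes.
#' @return matrix \code{[O, V]} (spatial singlet convention).
#' @export
sigma1_from_core <- function(core, Vp, Bpairs, O, V) {
  Vun <- array(Vp, dim = c(O, V, ncol(Vp)))
  out <- matrix(0, O, V)
  for (tm in .sigma1_terms) for (bp in Bpairs) {
    ops <- .tucker_ops(tm$w, core, Vun)
    ops[[length(ops) + 1L]] <- list(a = .bslice(bp[[1]], tm$int[1], tm$int[2], O),
                                    lab = paste0(tm$int[1], tm$int[2], "Q"))
    ops[[length(ops) + 1L]] <- list(a = .bslice(bp[[2]], tm$int[3], tm$int[4], O),
                                    lab = paste0(tm$int[3], tm$int[4], "Q"))
    out <- out + tm$c * tn_contract(ops, "ia")
  }
  out
}

#' Factorized doubles contribution of compressed triples
#'
#' As \code{\link{sigma1_from_core}} for the doubles block; includes the
#' occupied-virtual Fock terms.  The output is returned in the spatial
#' singlet (alpha-beta block) convention and is pair-symmetrized.
#'
#' @inheritParams sigma1_from_core
#' @param Fov occupied-virtual block of the (dressed or derivative-dressed)
#'   Fock matrix, \code{[O, V]}.
#' @export
sigma2_from_core <- function(core, Vp, Bpairs, Fov, O, V) {
  Vun <- array(Vp, dim = c(O, V, ncol(Vp)))
  out <- array(0, dim = c(O, O, V, V))
  for (tm in .sigma2_terms) {
    if (identical(tm$int, "F")) {
      ops <- .tucker_ops(tm$w, core, Vun)
      ops[[length(ops) + 1L]] <- list(a = Fov, lab = "me")
      out <- out + tm$c * tn_contract(ops, "ijab")
    } else {
      for (bp in Bpairs) {
        ops <- .tucker_ops(tm$w, core, Vun)
        ops[[length(ops) + 1L]] <- list(a = .bslice(bp[[1]], tm$int[1], tm$int[2], O),
                                        lab = paste0(tm$int[1], tm$int[2], "Q"))
        ops[[length(ops) + 1L]] <- list(a = .bslice(bp[[2]], tm$int[3], tm$int[4], O),
                                        lab = paste0(tm$int[3], tm$int[4], "Q"))
        out <- out + tm$c * tn_contract(ops, "ijab")
      }
    }
  }
  (out + tperm("ijab->jiba", out)) / 2
}

# ---- factorized projected generator (core equation) -----------------------

# gamma-diagram operand lists (without projector attachments):
# diagram A: + sum_d d2[i,j,a,d] (bd|ck);  diagram B: - sum_l d2[i,l,a,b] (lj|ck)
.gamma_diagrams <- function(d2, Bpairs, O) {
  out <- list()
  for (bp in Bpairs) {
    out[[length(out) + 1L]] <- list(
      sign = 1,
      ops = list(list(a = d2, lab = "ijad"),
                 list(a = .bslice(bp[[1]], "b", "d", O), lab = "bdQ"),
                 list(a = .bslice(bp[[2]], "c", "k", O), lab = "ckQ")))
    out[[length(out) + 1L]] <- list(
      sign = -1,
      ops = list(list(a = d2, lab = "ilab"),
                 list(a = .bslice(bp[[1]], "l", "j", O), lab = "ljQ"),
                 list(a = .bslice(bp[[2]], "c", "k", O), lab = "ckQ")))
  }
  out
}

#' Projected triples generator gamma-hat
#'
#' Computes \code{gamma_hat[X,Y,Z] = sum gamma_ijk^abc V[ia,X] V[jb,Y] V[kc,Z]}
#' without forming the rank-6 generator.  The core tensor then follows by
#' symmetrizing over (X,Y,Z) and dividing by the shifted canonical
#' denominators (see \code{\link{compute_core}}).
#'
#' @param d2 spatial doubles \code{[i,j,a,b]} (pair-symmetric).
#' @param Bpairs factor pairs as in \code{\link{sigma1_from_core}}.
#' @param Vp projector \code{[O*V, N]}; @param O,V space sizes.
#' @export
gamma_projected <- function(d2, Bpairs, Vp, O, V) {
  Vun <- array(Vp, dim = c(O, V, ncol(Vp)))
  N <- ncol(Vp)
  out <- array(0, dim = c(N, N, N))
  for (dg in .gamma_diagrams(d2, Bpairs, O)) {
    ops <- dg$ops
    ops[[length(ops) + 1L]] <- list(a = Vun, lab = "iaX")
    ops[[length(ops) + 1L]] <- list(a = Vun, lab = "jbY")
    ops[[length(ops) + 1L]] <- list(a = Vun, lab = "kcZ")
    out <- out + dg$sign * tn_contract(ops, "XYZ")
  }
  out
}

#' Compressed core tensor from the projected generator
#'
#' Applies the (X,Y,Z) permutation sum (the projected image of the P3 pair
#' symmetrization) and divides by the shifted canonical denominators
#' \code{omega - eps_X - eps_Y - eps_Z}.
#'
#' @param gamma_hat array \code{[N,N,N]} from \code{\link{gamma_projected}}.
#' @param eps_x canonical values of the projected one-body spectrum.
#' @param omega shift (0 for the ground state).
#' @param guard minimum |denominator| (hartree) before an intruder-state
#'   error is raised.
#' @export
compute_core <- function(gamma_hat, eps_x, omega = 0, guard = 1e-6) {
  N <- length(eps_x)
  sym <- 0
  for (p in .p3_perms) sym <- sym + aperm(gamma_hat, p)
  den <- omega - outer(outer(eps_x, eps_x, "+"), eps_x, "+")
  bad <- which(abs(den) < guard, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("near-singular triples denominator |omega - eps_X - eps_Y - eps_Z| < ",
         format(guard), " at (X,Y,Z) = (",
         paste(bad[1, ], collapse = ","), ")")
  sym / den
}

# ---- HOOI amplitude providers ---------------------------------------------

# index-scaling helper: multiply arr along dimension d by s[index]
.scale_dim <- function(arr, d, s) {
  dm <- dim(arr)
  shape <- rep(1, length(dm)); shape[d] <- dm[d]
  arr * array(rep(s, each = prod(dm[seq_len(d - 1L)])), dim = dm)
}

#' Partially projected guess-amplitude provider
#'
#' Returns a function \code{(Vy, Vz) -> R[u, Y, Z]} computing the partial
#' projection of the (T)-type guess tensor \code{P3 gamma(d2) / (shift - D)}
#' over two modes, at reduced cost using the Laplace separation of the
#' inverse denominator; the rank-6 tensor is never formed.  With \code{d2 =
#' T2} and \code{shift = 0} this is the ground-state provider; with
#' \code{d2 = R2-CCSD} and \code{shift = omega-CCSD} the excited-state one.
#'
#' @param d2 spatial doubles; @param B dressed factor array.
#' @param eps_o,eps_v orbital energies; @param shift energy shift (hartree).
#' @param quad optional prebuilt \code{laplace_quadrature}; built on the
#'   true denominator range when omitted.
#' @param laplace_tol quadrature tolerance.
#' @export
pt_triples_provider <- function(d2, B, eps_o, eps_v, shift = 0, quad = NULL,
                                laplace_tol = 1e-6) {
  O <- length(eps_o); V <- length(eps_v)
  dmin <- 3 * (min(eps_v) - max(eps_o))
  dmax <- 3 * (max(eps_v) - min(eps_o))
  if (is.null(quad))
    quad <- build_laplace_quadrature(dmin, dmax, shift = shift,
                                     tol = laplace_tol)
  laplace_assert(quad, dmin, dmax, tol = laplace_tol * 1.0000001)
  # per-point scaled inputs: e^{-t D} factorizes over the six free indices;
  # the internal summation index cancels between amplitude and integral.
  points <- lapply(seq_along(quad$t), function(k) {
    t_k <- quad$t[k]
    so <- exp(t_k * eps_o); sv <- exp(-t_k * eps_v)
    d2s <- d2
    d2s <- .scale_dim(d2s, 1L, so); d2s <- .scale_dim(d2s, 2L, so)
    d2s <- .scale_dim(d2s, 3L, sv); d2s <- .scale_dim(d2s, 4L, sv)
    sall <- c(so, sv); sinv <- c(1 / so, 1 / sv)
    list(w = quad$w[k], d2s = d2s, sall = sall, sinv = sinv)
  })
  function(Vy, Vz) {
    N_y <- ncol(Vy); N_z <- ncol(Vz)
    Vyu <- array(Vy, dim = c(O, V, N_y))
    Vzu <- array(Vz, dim = c(O, V, N_z))
    out <- array(0, dim = c(O * V, N_y, N_z))
    for (pt in points) {
      # d2 is scaled on all four indices; internal integral indices carry the
      # inverse factor so that only the six external indices remain scaled.
      BA1 <- .scale_dim(.scale_dim(B, 1L, pt$sall), 2L, pt$sinv)  # (b d|
      BA2 <- .scale_dim(.scale_dim(B, 1L, pt$sall), 2L, pt$sall)  # (c k|
      BB1 <- .scale_dim(.scale_dim(B, 1L, pt$sinv), 2L, pt$sall)  # (l j|
      for (assign in .p3_perms) {
        # assign[s] = role of gamma slot s: 1 = free, 2 = Y, 3 = Z
        role <- integer(3); role[assign] <- 1:3
        lab_free <- c("ia", "jb", "kc")
        attach <- function(ops) {
          outlab <- NULL
          for (s in 1:3) {
            sl <- substr(lab_free[s], 1, 1); vl <- substr(lab_free[s], 2, 2)
            if (role[s] == 1L) outlab <- paste0(sl, vl)
            else if (role[s] == 2L)
              ops[[length(ops) + 1L]] <- list(a = Vyu, lab = paste0(sl, vl, "Y"))
            else
              ops[[length(ops) + 1L]] <- list(a = Vzu, lab = paste0(sl, vl, "Z"))
          }
          list(ops = ops, out = paste0(outlab, "YZ"))
        }
        aA <- attach(list(list(a = pt$d2s, lab = "ijad"),
                          list(a = .bslice(BA1, "b", "d", O), lab = "bdQ"),
                          list(a = .bslice(BA2, "c", "k", O), lab = "ckQ")))
        tA <- tn_contract(aA$ops, aA$out)
        aB <- attach(list(list(a = pt$d2s, lab = "ilab"),
                          list(a = .bslice(BB1, "l", "j", O), lab = "ljQ"),
                          list(a = .bslice(BA2, "c", "k", O), lab = "ckQ")))
        tB <- tn_contract(aB$ops, aB$out)
        contrib <- array(tA - tB, dim = c(O * V, N_y, N_z))
        out <- out - pt$w * contrib     # 1/(shift - D) = -sum w e^{-t(D-shift)}
      }
    }
    out
  }
}

#' Excited-state guess-amplitude provider
#'
#' The excited-state analogue of \code{\link{pt_triples_provider}}: the
#' ground-state doubles are replaced by the EOM-CCSD doubles and the
#' denominator is shifted by the EOM-CCSD excitation energy.  With
#' \code{omega_ccsd = 0} and \code{r2_ccsd = T2} it coincides with the
#' ground-state provider.
#'
#' @param r2_ccsd spatial EOM-CCSD doubles \code{[i,j,a,b]}.
#' @param omega_ccsd EOM-CCSD excitation energy (hartree).
#' @inheritParams pt_triples_provider
#' @export
excited_triples_provider <- function(r2_ccsd, omega_ccsd, B, eps_o, eps_v,
                                     quad = NULL, laplace_tol = 1e-6) {
  pt_triples_provider(r2_ccsd, B, eps_o, eps_v, shift = omega_ccsd,
                      quad = quad, laplace_tol = laplace_tol)
}
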