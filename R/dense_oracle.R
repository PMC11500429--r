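# Dense canonical oracle for the triples equations.
#
# Brute-force implementations at oracle scale: rank-6 tensors are formed
# explicitly, contractions follow the defining sums index by index, and the
# dressing uses dense four-index transforms.  Nothing here shares contraction
# code with the factorized rank-reduced path, so agreement between the two is
# evidence of correctness.  A hard size guard refuses systems beyond desk
# scale.

.oracle_guard <- function(O, V) {
  if (O * V > 40L)
    stop("dense oracle size guard: O*V = ", O * V, " exceeds 40")
}

#' Reconstruct a dense triples tensor from its Tucker representation
#'
#' Explicit triple sum over the rank indices.
#' @param core \code{[N,N,N]}; @param Vp projector \code{[O*V, N]};
#' @param O,V space sizes.
#' @export
reconstruct_tucker <- function(core, Vp, O, V) {
  .oracle_guard(O, V)
  N <- ncol(Vp)
  w <- array(0, dim = c(O, O, O, V, V, V))
  for (X in seq_len(N)) for (Y in seq_len(N)) for (Z in seq_len(N)) {
    cXYZ <- core[X, Y, Z]
    if (cXYZ == 0) next
    vx <- array(Vp[, X], dim = c(O, V))
    vy <- array(Vp[, Y], dim = c(O, V))
    vz <- array(Vp[, Z], dim = c(O, V))
    w <- w + cXYZ * aperm(outer(outer(vx, vy), vz), c(1, 3, 5, 2, 4, 6))
  }
  w
}

#' Project a dense triples tensor onto a Tucker basis (oracle)
#'
#' @param w dense \code{[O,O,O,V,V,V]}; @param Vp projector.
#' @export
project_triples <- function(w, Vp, O, V) {
  .oracle_guard(O, V)
  N <- ncol(Vp)
  wp <- aperm(w, c(1, 4, 2, 5, 3, 6))
  dim(wp) <- c(O * V, O * V, O * V)
  out <- array(0, dim = c(N, N, N))
  for (X in seq_len(N)) for (Y in seq_len(N)) for (Z in seq_len(N)) {
    acc <- 0
    for (u1 in seq_len(O * V)) {
      vy <- Vp[, Y]; vz <- Vp[, Z]
      acc <- acc + Vp[u1, X] * sum(wp[u1, , ] * outer(vy, vz))
    }
    out[X, Y, Z] <- acc
  }
  out
}

# dense T1 dressing of the full spatial Hamiltonian (no factorization)
dress_dense <- function(h, g, t1, n_occ) {
  n <- nrow(h); nv <- n - n_occ
  Tm <- matrix(0, n, n)
  Tm[n_occ + seq_len(nv), seq_len(n_occ)] <- t(t1)
  Lc <- diag(n) - Tm; La <- diag(n) + t(Tm)
  gt <- g
  gt <- ein2("Pp,pqrs->Pqrs", Lc, gt)
  gt <- ein2("Qq,pqrs->pQrs", La, gt)
  gt <- ein2("Rr,pqrs->pqRs", Lc, gt)
  gt <- ein2("Ss,pqrs->pqrS", La, gt)
  ht <- Lc %*% h %*% t(La)
  occ <- seq_len(n_occ)
  J <- apply(gt[, , occ, occ, drop = FALSE], c(1, 2),
             function(m) sum(diag(as.matrix(m))))
  K <- matrix(0, n, n)
  for (j in occ) K <- K + gt[, j, j, ]
  list(h = ht, g = gt, fock = ht + 2 * J - K)
}

# dense derivative dressing (direction r1) of an already dressed (h, g)
dress_dense_derivative <- function(hd, gd, r1, n_occ) {
  n <- nrow(hd); nv <- n - n_occ
  Rm <- matrix(0, n, n)
  Rm[n_occ + seq_len(nv), seq_len(n_occ)] <- t(r1)
  dLc <- -Rm; dLa <- t(Rm)
  gp <- ein2("Pp,pqrs->Pqrs", dLc, gd) + ein2("Qq,pqrs->pQrs", dLa, gd) +
    ein2("Rr,pqrs->pqRs", dLc, gd) + ein2("Ss,pqrs->pqrS", dLa, gd)
  hp <- dLc %*% hd + hd %*% t(dLa)
  occ <- seq_len(n_occ)
  J <- apply(gp[, , occ, occ, drop = FALSE], c(1, 2),
             function(m) sum(diag(as.matrix(m))))
  K <- matrix(0, n, n)
  for (j in occ) K <- K + gp[, j, j, ]
  list(h = hp, g = gp, fock = hp + 2 * J - K)
}

#' Dense triples generator gamma (naive loops)
#'
#' Explicit sums over the internal index for both diagrams; \code{g} is the
#' dense (possibly derivative-) dressed chemist integral tensor.
#' @param d2 spatial doubles \code{[i,j,a,b]}; @param g dense integrals;
#' @param O,V space sizes.
#' @export
dense_gamma <- function(d2, g, O, V) {
  .oracle_guard(O, V)
  gam <- array(0, dim = c(O, O, O, V, V, V))
  for (i in 1:O) for (j in 1:O) for (k in 1:O)
    for (a in 1:V) for (b in 1:V) for (c in 1:V) {
      acc <- 0
      for (d in 1:V)
        acc <- acc + d2[i, j, a, d] * g[O + b, O + d, O + c, k]
      for (l in 1:O)
        acc <- acc - d2[i, l, a, b] * g[l, j, O + c, k]
      gam[i, j, k, a, b, c] <- acc
    }
  gam
}

#' Solve the dense triples equation (oracle)
#'
#' Applies the P3 pair symmetrization with explicit permutation loops and
#' divides element-wise by \code{omega - (eps_abc - eps_ijk)}.
#' @param gam generator from \code{\link{dense_gamma}} (sums of diagrams).
#' @param eps_o,eps_v orbital energies; @param omega shift.
#' @export
solve_dense_r3 <- function(gam, eps_o, eps_v, omega = 0) {
  O <- length(eps_o); V <- length(eps_v)
  .oracle_guard(O, V)
  sym <- array(0, dim = dim(gam))
  for (p in .p3_perms) sym <- sym + aperm(gam, c(p, p + 3L))
  den <- omega - triples_denominator(eps_o, eps_v)
  sym / den
}

# naive evaluation of one sigma-from-triples table term
.naive_term <- function(tm, g, Fov, w, O, V, out_labels) {
  frees <- .parse_idx(out_labels)
  dummies <- setdiff(unique(c(tm$int, tm$w)), c(frees, "F"))
  is_occ <- function(l) l %in% .occ_labels
  rng <- lapply(dummies, function(l) seq_len(if (is_occ(l)) O else V))
  names(rng) <- dummies
  grid <- do.call(expand.grid, rng)
  dims_out <- vapply(frees, function(l) if (is_occ(l)) O else V, numeric(1))
  out <- array(0, dim = dims_out)
  gidx <- function(l, val) if (is_occ(l)) val else O + val
  for (r in seq_len(max(1L, nrow(grid)))) {
    vals <- if (nrow(grid)) as.list(grid[r, , drop = FALSE]) else list()
    lookup <- function(l) vals[[l]]
    # integral part: free labels of the integral stay as slices
    if (identical(tm$int, "F")) {
      ival <- Fov[lookup("m"), lookup("e")]
      int_free <- character(0)
    } else {
      int_free <- intersect(tm$int, frees)
      ix <- lapply(tm$int, function(l)
        if (l %in% int_free) {
          if (is_occ(l)) seq_len(O) else O + seq_len(V)
        } else gidx(l, lookup(l)))
      ival <- g[ix[[1]], ix[[2]], ix[[3]], ix[[4]]]
    }
    w_free <- intersect(tm$w, frees)
    wx <- lapply(tm$w, function(l)
      if (l %in% w_free) seq_len(if (is_occ(l)) O else V) else lookup(l))
    wval <- w[wx[[1]], wx[[2]], wx[[3]], wx[[4]], wx[[5]], wx[[6]]]
    dms <- function(ls) vapply(ls, function(l) if (is_occ(l)) O else V,
                               numeric(1))
    if (length(int_free) == 0L) {
      piece <- ival * wval                       # ival scalar
      dim(piece) <- dms(w_free)
    } else {
      piece <- outer(as.numeric(ival), as.numeric(wval))
      dim(piece) <- c(dms(int_free), dms(w_free))
    }
    out <- out + aperm(piece, match(frees, c(int_free, w_free)))
  }
  tm$c * out
}

#' Dense sigma contributions of a triples tensor (naive loops)
#'
#' Evaluates the frozen singles/doubles contraction tables by direct
#' summation over the dummy indices; reference values for the factorized
#' operations.
#' @param w dense triples; @param g dense dressed integrals; @param Fov
#'   occupied-virtual Fock block; @param O,V sizes.
#' @return list \code{s1} \code{[O,V]}, \code{s2} \code{[O,O,V,V]}.
#' @export
dense_sigma_triples <- function(w, g, Fov, O, V) {
  .oracle_guard(O, V)
  s1 <- array(0, dim = c(O, V))
  for (tm in .sigma1_terms) s1 <- s1 + .naive_term(tm, g, Fov, w, O, V, "ia")
  s2 <- array(0, dim = c(O, O, V, V))
  for (tm in .sigma2_terms) s2 <- s2 + .naive_term(tm, g, Fov, w, O, V, "ijab")
  s2 <- (s2 + tperm("ijab->jiba", s2)) / 2
  list(s1 = s1, s2 = s2)
}
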