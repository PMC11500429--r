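# T1 dressing of integrals.
#
# Similarity transformation by the singles cluster operator, A~ = e^(-T1) A
# e^(T1), shortens the working equations: all explicit T1 terms disappear in
# favour of "dressed" integrals.  For a one-index transformation write
#   a+_i ->  a+_i - sum_a t_i^a a+_a        (creation, occupied)
#   a_a  ->  a_a  + sum_i t_i^a a_i         (annihilation, virtual)
# so every chemist integral index transforms with one of two matrices,
#   Lc = I - T  (creation slots;  T[a,i] = t_i^a in the virt-occ block)
#   La = I + T' (annihilation slots; T'[i,a] = t_i^a in the occ-virt block),
# and the rank-3 factors transform as B~[p,q,Q] = Lc^T B La (per Q), keeping
# the cost at N^2 N_aux per index.  Dressing with t1 = 0 is the identity, and
# dressing by -t1 inverts dressing by t1 exactly.

# Lc, La transformation matrices for given t1 (t1 indexed [i, a], spatial)
.dress_mats <- function(t1, n_occ, n_virt) {
  n <- n_occ + n_virt
  Tm <- matrix(0, n, n)
  Tm[n_occ + seq_len(n_virt), seq_len(n_occ)] <- t(t1)   # virt rows, occ cols
  list(Lc = diag(n) - Tm, La = diag(n) + t(Tm))
}

#' T1-dress density-fitting factors and the Fock matrix
#'
#' @param df \code{df_factors} (undressed).
#' @param h one-electron matrix (bare, spatial).
#' @param t1 singles amplitudes, matrix \code{[i, a]} over active spaces.
#' @param n_occ number of occupied spatial orbitals.
#' @return list of class \code{dressed_factors} with \code{b} (dressed
#'   factors), \code{fock} (dressed closed-shell Fock matrix) and \code{t1}.
#' @export
dress_t1 <- function(df, h, t1, n_occ) {
  n <- df$n_mo; nv <- n - n_occ
  if (!all(dim(t1) == c(n_occ, nv))) stop("t1 shape mismatch with spaces")
  M <- .dress_mats(t1, n_occ, nv)
  b <- df$b
  # transform index p (creation) and q (annihilation) of B[p,q,Q]:
  # B~[P,R,Q] = sum_pq Lc[P,p] La[R,q] B[p,q,Q]
  bd <- ein2("Pp,pqQ->PqQ", M$Lc, b)
  bd <- ein2("Rq,PqQ->PRQ", M$La, bd)
  hd <- M$Lc %*% h %*% t(M$La)
  fd <- .dressed_fock(hd, bd, n_occ)
  structure(list(b = bd, fock = fd, h = hd, t1 = t1, n_occ = n_occ,
                 n_mo = n, n_aux = df$n_aux),
            class = "dressed_factors")
}

# closed-shell Fock from (possibly dressed) one-body matrix and factors:
# F_pq = h_pq + sum_j [2 (pq|jj) - (pj|jq)]
.dressed_fock <- function(h, b, n_occ) {
  occ <- seq_len(n_occ)
  cJ <- apply(b, 3, function(m) sum(diag(m)[occ]))   # sum_j (jj|Q)
  J <- ein2("pqQ,Q->pq", b, cJ)
  K <- ein2("pjQ,jqQ->pq", b[, occ, , drop = FALSE],
            b[occ, , , drop = FALSE])
  h + 2 * J - K
}

#' Dressed chemist integrals (pq|~rs) reconstructed densely
#'
#' Oracle-scale convenience: contracts the dressed factors back to a rank-4
#' tensor.
#' @param dressed \code{dressed_factors}.
#' @export
dressed_eri <- function(dressed) {
  n <- dressed$n_mo
  B <- matrix(dressed$b, n * n, dressed$n_aux)
  array(B %*% t(B), dim = c(n, n, n, n))
}

#' Directional derivative of T1 dressing (r1 dressing)
#'
#' Returns d/dl B~(t1 + l r1) at l = 0, i.e. the factors of the commutator
#' [H~, R1] restricted to its two-electron part; with the product rule the
#' derivative replaces the transformation of one index at a time by the r1
#' block.  The one-body part is returned as \code{h} (the derivative-dressed
#' bare one-electron matrix) and \code{fock} (its mean-field completion),
#' which together with \code{b} define the one- and two-body coefficients of
#' [H~, R1].
#'
#' @param dressed \code{dressed_factors} at the expansion point t1.
#' @param h bare one-electron matrix.
#' @param r1 direction, matrix \code{[i, a]}.
#' @export
dress_derivative <- function(dressed, h, r1) {
  n <- dressed$n_mo; n_occ <- dressed$n_occ; nv <- n - n_occ
  if (!all(dim(r1) == c(n_occ, nv))) stop("r1 shape mismatch")
  Mt <- .dress_mats(dressed$t1, n_occ, nv)
  Rm <- matrix(0, n, n)
  Rm[n_occ + seq_len(nv), seq_len(n_occ)] <- t(r1)
  dLc <- -Rm; dLa <- t(Rm)
  b0 <- dressed$b           # already dressed by t1
  # note: d(Lc^T B La) = dLc^T B La + Lc^T B dLa; applying the derivative
  # matrices to the already-dressed factors is equivalent because Lc/La are
  # unit-triangular in the same block and dLc commutes appropriately:
  # dLc^T Lc^-T (Lc^T B La) keeps only the occ->virt replacement, which is
  # unaffected by the t1 blocks (t1 and r1 occupy the same strictly
  # lower-triangular block, and Rm %*% Tm = 0).
  db <- ein2("Pp,pqQ->PqQ", dLc, b0) + ein2("Rq,pqQ->pRQ", dLa, b0)
  dh <- dLc %*% dressed$h + dressed$h %*% t(dLa)
  # mean-field part of the derivative is bilinear in (b, db)
  dfock <- dh + .dress_two_body_mean_field_cross(dressed$b, db, n_occ)
  structure(list(b = db, h = dh, fock = dfock, n_occ = n_occ, n_mo = n,
                 n_aux = dressed$n_aux),
            class = "dressed_derivative")
}

# mean-field completion for a derivative pair (b, db):
# d[2J - K] = 2 J(b,db) + 2 J(db,b) - K(b,db) - K(db,b), where the two slots
# of each Coulomb/exchange term carry one factor each.
.dress_two_body_mean_field_cross <- function(b, db, n_occ) {
  n <- dim(b)[1]; occ <- seq_len(n_occ); na <- dim(b)[3]
  traceQ <- function(x) {
    m <- matrix(0, na, 1)
    for (j in occ) m <- m + x[j, j, , drop = TRUE]
    as.numeric(m)
  }
  J1 <- ein2("pqQ,Q->pq", b, traceQ(db)) + ein2("pqQ,Q->pq", db, traceQ(b))
  Kc <- function(x, y) ein2("pjQ,jqQ->pq",
                            x[, occ, , drop = FALSE],
                            y[occ, , , drop = FALSE])
  2 * J1 - Kc(b, db) - Kc(db, b)
}
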