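# Higher-order orthogonal iteration (HOOI) for the triples projectors.
#
# The Tucker factor shared by the three pair modes of the (symmetric) guess
# tensor is computed by alternating least squares: each iteration contracts
# the guess tensor with the current projector over two modes (the provider's
# partial projection, evaluated at reduced cost with Laplace-separated
# denominators), takes the leading left singular vectors of the unfolding,
# and repeats until the decomposition error stops improving.  Because the
# tensor norm is fixed, the captured variance (the Frobenius norm of the
# projected core) is an equivalent, monotone convergence measure and is used
# as the error surrogate.  Oscillations between two subspaces - observed for
# excited-state amplitudes - are quenched by the stacked-SVD damping step.

#' Stacked-SVD damping step
#'
#' Stacks two successive projectors into an OV x 2N matrix and returns the
#' leading left singular vectors: an orthonormal projector whose span is
#' contained in the union of the two input spans.
#'
#' @param v_prev,v_curr orthonormal projectors \code{[OV, N]}.
#' @export
stacked_svd_damping <- function(v_prev, v_curr) {
  stopifnot(ncol(v_prev) == ncol(v_curr))
  N <- ncol(v_curr)
  sv <- svd(cbind(v_prev, v_curr))
  if (sv$d[N] < 1e-12)
    stop("stacked projector matrix is rank deficient below the requested rank")
  sv$u[, seq_len(N), drop = FALSE]
}

#' Canonicalize a triples projector
#'
#' Rotates the projector columns so that the projected one-body energy matrix
#' G_XY = sum_ia V[ia,X] (eps_a - eps_i) V[ia,Y] becomes diagonal with
#' ascending eigenvalues eps_X, removing the rotational ambiguity of the
#' subspace basis; the span is unchanged.  Signs are fixed deterministically
#' (largest-magnitude component positive).
#'
#' @param v orthonormal projector \code{[O*V, N]}.
#' @param eps_o,eps_v orbital energies.
#' @return list \code{v} (rotated projector), \code{eps} (canonical values).
#' @export
canonicalize_projector <- function(v, eps_o, eps_v) {
  O <- length(eps_o); V <- length(eps_v)
  delta <- as.numeric(outer(-eps_o, eps_v, "+"))   # eps_a - eps_i, occ fast
  G <- t(v) %*% (v * delta)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  vr <- v %*% ev$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vr))) {
    m <- which.max(abs(vr[, k]))
    if (vr[m, k] < 0) vr[, k] <- -vr[, k]
  }
  list(v = vr, eps = ev$values[ord])
}

#' HOOI decomposition of a triples guess tensor
#'
#' @param provider function \code{(Vy, Vz) -> R[u, Y, Z]} returning the
#'   partial projection of the guess tensor (see
#'   \code{\link{pt_triples_provider}}).
#' @param rank requested subspace size N (clipped to O*V with a warning).
#' @param nov compound pair dimension O*V.
#' @param init optional starting projector \code{[nov, rank]}; defaults to a
#'   seeded random orthonormal basis.
#' @param max_iter iteration cap; @param tol relative change of the captured
#'   variance below which the iteration stops.
#' @param damping enable stacked-SVD damping on oscillation (default TRUE).
#' @param max_damp consecutive damped steps allowed before declaring failure.
#' @param seed seed for the default initialization.
#' @return list \code{v} (orthonormal projector), \code{surrogate} (captured
#'   variance at the accepted iterate), \code{history}, \code{iterations}.
#' @export
hooi_decompose <- function(provider, rank, nov, init = NULL, max_iter = 50L,
                           tol = 1e-4, damping = TRUE, max_damp = 5L,
                           seed = 1L) {
  if (rank > nov) {
    warning("requested rank ", rank, " exceeds O*V = ", nov, "; clipped")
    rank <- nov
  }
  if (rank < 1L) stop("rank must be at least 1")
  if (is.null(init)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    init <- qr.Q(qr(matrix(stats::rnorm(nov * rank), nov, rank)))
  }
  v <- init[, seq_len(rank), drop = FALSE]
  surr_old <- -Inf
  v_prev <- NULL
  history <- numeric(0)
  n_damp <- 0L; worse <- 0L
  for (it in seq_len(max_iter)) {
    R <- provider(v, v)
    M1 <- matrix(R, nov, rank * rank)
    sv <- svd(M1, nu = rank, nv = 0)
    v_new <- sv$u[, seq_len(rank), drop = FALSE]
    surr <- sum(sv$d[seq_len(rank)]^2)    # captured variance (monotone)
    if (surr < surr_old * (1 - 1e-12) && damping && !is.null(v_prev)) {
      n_damp <- n_damp + 1L
      v_new <- stacked_svd_damping(v, v_new)
      R <- provider(v_new, v_new)
      M1 <- matrix(R, nov, rank * rank)
      sv <- svd(M1, nu = rank, nv = 0)
      v_new2 <- sv$u[, seq_len(rank), drop = FALSE]
      surr <- sum(sv$d[seq_len(rank)]^2)
      v_new <- v_new2
      if (surr < surr_old * (1 - 1e-12)) {
        worse <- worse + 1L
        if (worse >= 2L || n_damp > max_damp) {
          history <- c(history, surr)
          break       # keep the previous accepted iterate
        }
      } else worse <- 0L
    }
    history <- c(history, surr)
    if (surr >= surr_old * (1 - 1e-12)) {
      v_prev <- v
      v <- v_new
      if (is.finite(surr_old) && surr_old > 0 &&
          abs(surr - surr_old) / surr < tol) { surr_old <- max(surr, surr_old); break }
      surr_old <- max(surr, surr_old)
    }
  }
  list(v = v, surrogate = surr_old, history = history, iterations = length(history))
}

#' Provider backed by an explicit dense tensor (oracle-scale)
#'
#' Wraps a dense pair-symmetric triples tensor as a partial-projection
#' provider, for verification and for exact-rank recovery tests.
#' @param w dense tensor \code{[O,O,O,V,V,V]}; @param O,V sizes.
#' @export
dense_provider <- function(w, O, V) {
  .oracle_guard(O, V)
  nov <- O * V
  M <- aperm(w, c(1, 4, 2, 5, 3, 6))
  dim(M) <- c(nov, nov, nov)
  function(Vy, Vz) {
    out <- array(0, dim = c(nov, ncol(Vy), ncol(Vz)))
    for (u in seq_len(nov)) out[u, , ] <- t(Vy) %*% M[u, , ] %*% Vz
    out
  }
}
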