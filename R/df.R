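# Density-fitting / Cholesky factorization of the two-electron integrals.
#
# The triples machinery consumes the ERIs only through rank-3 factors
# B[p,q,Q] with (pq|rs) = sum_Q B[p,q,Q] B[r,s,Q].  Factors come either from
# a pivoted Cholesky decomposition of the dense integral tensor (viewed as a
# symmetric PSD matrix over compound pair indices) or from backend-supplied
# three-center integrals and a two-center metric.

#' Density-fitting factors
#'
#' @param b rank-3 array \code{b[p,q,Q]}.
#' @return object of class \code{df_factors}.
#' @export
df_factors <- function(b) {
  stopifnot(length(dim(b)) == 3L)
  structure(list(b = b, n_aux = dim(b)[3], n_mo = dim(b)[1]),
            class = "df_factors")
}

#' @export
print.df_factors <- function(x, ...) {
  cat("df_factors: N_MO =", x$n_mo, " N_aux =", x$n_aux, "\n")
  invisible(x)
}

#' Reconstruct (pq|rs) from factors
#' @param df \code{df_factors}.
#' @export
df_reconstruct <- function(df) {
  n <- df$n_mo
  B <- matrix(df$b, n * n, df$n_aux)
  array(B %*% t(B), dim = c(n, n, n, n))
}

#' Pivoted-Cholesky factorization of dense ERIs
#'
#' Treats (pq|rs) as a symmetric positive-semidefinite matrix over compound
#' pair indices and runs pivoted Cholesky until the largest remaining diagonal
#' is below \code{tol}; the maximum absolute reconstruction error is then
#' bounded by the stopping diagonal (and is verified).
#'
#' @param ints \code{mo_integrals}.
#' @param tol stopping threshold on the residual diagonal (default 1e-8).
#' @return \code{df_factors} with \code{n_aux <=} number of pairs.
#' @export
cholesky_factorize <- function(ints, tol = 1e-8) {
  n <- ints$n_mo
  M <- matrix(ints$g, n * n, n * n)
  np <- n * n
  d <- diag(M)
  if (min(d) < -tol)
    stop("non-PSD integral matrix: negative diagonal ", format(min(d)))
  L <- matrix(0, np, 0)
  piv <- integer(0)
  repeat {
    dmax <- max(d)
    if (dmax <= tol || ncol(L) >= np) break
    p <- which.max(d)
    col <- M[, p]
    if (ncol(L) > 0) col <- col - L %*% L[p, ]
    if (col[p] < -tol) stop("non-PSD input: negative pivot ", format(col[p]))
    col <- col / sqrt(max(col[p], .Machine$double.eps))
    L <- cbind(L, as.numeric(col))
    d <- d - as.numeric(col)^2
    d[d < 0] <- 0
    piv <- c(piv, p)
  }
  df <- df_factors(array(L, dim = c(n, n, ncol(L))))
  err <- amax(df_reconstruct(df) - ints$g)
  if (err > 10 * max(tol, 1e-14))
    stop("Cholesky reconstruction error ", format(err), " exceeds tolerance")
  df
}

#' Factors from three-center integrals and a metric
#'
#' Computes B[p,q,Q] = sum_P (pq|P) [V^(-1/2)]_PQ via a symmetric eigenvalue
#' decomposition of the metric, so that sum_Q B_pq^Q B_rs^Q equals the
#' density-fitted integral (pq|P) V^(-1)_PP' (P'|rs).  The symmetric inverse
#' square root is one of the two common metric conventions (the other being a
#' Cholesky factor of V^(-1)); both reproduce the same fitted integrals.
#'
#' @param three_center array \code{(pq|P)}, dims n x n x n_aux.
#' @param metric symmetric positive-definite matrix V_PQ.
#' @export
build_df_factors <- function(three_center, metric) {
  stopifnot(length(dim(three_center)) == 3L)
  ev <- eigen((metric + t(metric)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("metric is not positive definite: smallest eigenvalue ",
         format(min(ev$values)))
  Vmh <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  n <- dim(three_center)[1]; na <- dim(three_center)[3]
  B <- matrix(three_center, n * n, na) %*% Vmh
  df_factors(array(B, dim = c(n, n, na)))
}
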