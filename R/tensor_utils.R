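# Dense tensor contraction helpers.
#
# All coupled-cluster working equations in this package are written as chains
# of pairwise contractions ("ij,jk->ik" style).  ein2() performs one pairwise
# contraction by permuting both operands to [free, contracted] order and
# calling a single matrix multiply, so every step is a GEMM; on the
# rank-reduced path the network contractor (tn_contract) additionally
# enforces the allocation contract on intermediate tensor orders.

.parse_idx <- function(s) strsplit(s, "")[[1]]

#' Pairwise tensor contraction
#'
#' Contracts two dense arrays according to an index specification of the form
#' \code{"abc,cd->abd"}.  Indices present in both inputs and absent from the
#' output are summed over.  Shared free (batch) indices are not supported;
#' rewrite the contraction chain instead.
#'
#' @param spec contraction specification string.
#' @param A,B numeric arrays (vectors are treated as 1-d arrays).
#' @return the contracted array, with dimensions ordered as in the output spec.
#' @keywords internal
ein2 <- function(spec, A, B) {
  parts <- strsplit(spec, "->", fixed = TRUE)[[1]]
  ins <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  stopifnot(length(ins) == 2L)
  ia <- .parse_idx(ins[1]); ib <- .parse_idx(ins[2])
  io <- if (length(parts) > 1L && nzchar(parts[2])) .parse_idx(parts[2]) else character(0)
  if (is.null(dim(A))) dim(A) <- length(A)
  if (is.null(dim(B))) dim(B) <- length(B)
  stopifnot(length(dim(A)) == length(ia), length(dim(B)) == length(ib))
  con <- intersect(ia, ib)
  if (any(con %in% io)) stop("batch (shared free) indices unsupported: ",
                             paste(intersect(con, io), collapse = ""))
  fa <- setdiff(ia, con); fb <- setdiff(ib, con)
  if (!setequal(io, c(fa, fb))) stop("output indices must be the free indices")
  dims <- c(stats::setNames(dim(A), ia), stats::setNames(dim(B), ib))
  dimc <- dims[con]
  pa <- match(c(fa, con), ia); pb <- match(c(con, fb), ib)
  Am <- matrix(aperm(A, pa), nrow = prod(dims[fa]), ncol = prod(dimc))
  Bm <- matrix(aperm(B, pb), nrow = prod(dimc), ncol = prod(dims[fb]))
  Cm <- Am %*% Bm
  out_free <- c(fa, fb)
  C <- array(Cm, dim = as.numeric(dims[out_free]))
  perm <- match(io, out_free)
  if (length(io) == 0L) return(as.numeric(Cm))
  aperm_keep(C, perm)
}

# aperm that tolerates 1-d arrays
aperm_keep <- function(x, perm) {
  if (length(dim(x)) <= 1L) return(x)
  aperm(x, perm)
}

#' Reorder tensor indices
#'
#' @param x array; @param spec e.g. "ijab->abij".
#' @keywords internal
tperm <- function(spec, x) {
  parts <- strsplit(spec, "->", fixed = TRUE)[[1]]
  from <- .parse_idx(parts[1]); to <- .parse_idx(parts[2])
  aperm(x, match(to, from))
}

# Frobenius norm and max-abs over arbitrary arrays
fnorm <- function(x) sqrt(sum(x * x))
amax <- function(x) if (length(x) == 0L) 0 else max(abs(x))

# numerical symmetrization helpers ------------------------------------------

# symmetrize an n^4 chemist-ordered ERI tensor to exact 8-fold symmetry
symmetrize8 <- function(g) {
  g <- (g + aperm(g, c(2, 1, 3, 4))) / 2
  g <- (g + aperm(g, c(1, 2, 4, 3))) / 2
  g <- (g + aperm(g, c(3, 4, 1, 2))) / 2
  g
}

max_asym8 <- function(g) {
  max(amax(g - aperm(g, c(2, 1, 3, 4))),
      amax(g - aperm(g, c(1, 2, 4, 3))),
      amax(g - aperm(g, c(3, 4, 1, 2))))
}
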