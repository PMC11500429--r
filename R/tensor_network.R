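# Small tensor-network contractor for the factorized (rank-reduced) path.
#
# A term is a list of (array, label-string) operands plus an output label
# string; the engine contracts operands pairwise, always through ein2 (one
# GEMM per step), choosing greedily the pair whose contraction yields the
# smallest intermediate.  The factorized triples contributions are expressed
# as such networks over the Tucker factors, the core tensor and the rank-3
# density-fitting factors, so no rank-6 tensor over occupied/virtual indices
# is ever formed; a guard asserts that no intermediate exceeds the allowed
# order.

#' Contract a tensor network
#'
#' @param ops list of \code{list(a = array, lab = "ija")} operands.
#' @param out output label string ("" for scalar).
#' @param max_order guard on intermediate tensor order (default 5).
#' @keywords internal
tn_contract <- function(ops, out, max_order = 5L) {
  out_lab <- .parse_idx(out)
  dims_of <- function(op) {
    d <- dim(op$a); if (is.null(d)) d <- length(op$a)
    stats::setNames(d, .parse_idx(op$lab))
  }
  while (length(ops) > 1L) {
    best <- NULL; best_size <- Inf; best_keep <- NULL
    for (i in seq_along(ops)) for (j in seq_along(ops)) {
      if (j <= i) next
      li <- .parse_idx(ops[[i]]$lab); lj <- .parse_idx(ops[[j]]$lab)
      shared <- intersect(li, lj)
      other_labs <- unique(unlist(lapply(ops[-c(i, j)],
                                         function(o) .parse_idx(o$lab))))
      ext <- union(other_labs, out_lab)
      if (length(intersect(shared, ext)) > 0L) next   # batch: ein2 unsupported
      if (length(shared) == 0L && length(ops) > 2L) next  # defer outer products
      keep <- setdiff(union(li, lj), shared)
      if (length(keep) > max_order) next              # honor the order guard
      dd <- c(dims_of(ops[[i]]), dims_of(ops[[j]]))
      size <- if (length(keep)) prod(dd[keep]) else 1
      if (size < best_size) { best <- c(i, j); best_size <- size; best_keep <- keep }
    }
    if (is.null(best))
      stop("tn_contract: no contraction path within the order guard (",
           max_order, ")")
    i <- best[1]; j <- best[2]
    spec <- paste0(ops[[i]]$lab, ",", ops[[j]]$lab, "->",
                   paste(best_keep, collapse = ""))
    newa <- ein2(spec, ops[[i]]$a, ops[[j]]$a)
    ops <- c(ops[-c(i, j)],
             list(list(a = newa, lab = paste(best_keep, collapse = ""))))
  }
  fin <- ops[[1]]
  if (nzchar(out)) {
    if (!setequal(.parse_idx(fin$lab), out_lab))
      stop("tn_contract: leftover labels '", fin$lab, "' vs requested '", out, "'")
    if (fin$lab != out) fin$a <- tperm(paste0(fin$lab, "->", out), fin$a)
    fin$a
  } else {
    sum(fin$a)
  }
}
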