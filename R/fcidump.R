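# FCIDUMP reader/writer (Molpro-style).
#
# Records are "value i j k l" with 1-based indices in chemist convention:
#   value (ij|kl)  : i,j,k,l > 0
#   value h_ij     : k = l = 0
#   value eps_i    : j = k = l = 0   (orbital-energy record, optional dialect)
#   value e_core   : i = j = k = l = 0
# Only symmetry-unique nonzero elements are written; 8-fold permutational
# symmetry is restored on read.

#' Read an FCIDUMP file
#'
#' @param path file path.
#' @param energies_from \code{"fock"} (default) rebuilds orbital energies from
#'   the closed-shell Fock diagonal; \code{"records"} takes them from
#'   orbital-energy records in the file.
#' @param check_canonical require a diagonal Fock matrix (default TRUE).
#' @return list with \code{spaces} and \code{ints}.
#' @export
read_fcidump <- function(path, energies_from = c("fock", "records"),
                         check_canonical = TRUE) {
  energies_from <- match.arg(energies_from)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # header: &FCI ... &END possibly spanning lines
  hdr_end <- grep("&END|/\\s*$", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP header: no &END terminator")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  get_int <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), hdr))[[1]]
    if (length(m) < 2L)
      stop("malformed FCIDUMP header: missing ", key, " (line 1)")
    as.integer(m[2])
  }
  n <- get_int("NORB")
  nelec <- get_int("NELEC")
  if (nelec %% 2L != 0L)
    stop("NELEC is odd: only closed-shell references are supported")
  h <- matrix(0, n, n)
  g <- array(0, dim = c(n, n, n, n))
  e_core <- 0
  eps_rec <- rep(NA_real_, n)
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in seq_along(body)) {
    tok <- strsplit(trimws(body[ln]), "\\s+")[[1]]
    if (length(tok) != 5L)
      stop("malformed FCIDUMP record at body line ", ln, ": '", body[ln], "'")
    v <- suppressWarnings(as.numeric(tok[1]))
    idx <- suppressWarnings(as.integer(tok[2:5]))
    if (is.na(v) || anyNA(idx))
      stop("malformed FCIDUMP record at body line ", ln, ": '", body[ln], "'")
    i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
    if (i > 0L && k > 0L) {
      for (pq in list(c(i, j), c(j, i)))
        for (rs in list(c(k, l), c(l, k))) {
          g[pq[1], pq[2], rs[1], rs[2]] <- v
          g[rs[1], rs[2], pq[1], pq[2]] <- v
        }
    } else if (i > 0L && j > 0L) {
      h[i, j] <- v; h[j, i] <- v
    } else if (i > 0L) {
      eps_rec[i] <- v
    } else {
      e_core <- v
    }
  }
  ints <- mo_integrals(h, g, n_electrons = nelec, e_core = e_core)
  if (energies_from == "records") {
    if (anyNA(eps_rec))
      stop("energies_from = 'records' but the file has no complete set of ",
           "orbital-energy records")
    n_occ <- nelec %/% 2L
    spaces <- orbital_spaces(n_occ, n - n_occ,
                             eps_occ = eps_rec[seq_len(n_occ)],
                             eps_virt = eps_rec[(n_occ + 1L):n])
  } else {
    spaces <- spaces_from_integrals(ints,
                                    tol = if (check_canonical) 1e-8 else Inf)
  }
  list(spaces = spaces, ints = ints)
}

#' Write an FCIDUMP file
#'
#' Writes only symmetry-unique nonzero two-electron records (p >= q,
#' (pq) >= (rs) in compound order), the unique one-electron records, optional
#' orbital-energy records and the core-energy record.
#'
#' @param spaces \code{orbital_spaces}; @param ints \code{mo_integrals}.
#' @param path output path.
#' @param write_energies also write orbital-energy records (default TRUE).
#' @param digits significant digits (default 17, round-trip exact).
#' @export
write_fcidump <- function(spaces, ints, path, write_energies = TRUE,
                          digits = 17L) {
  n <- ints$n_mo
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  fmt <- function(v, i, j, k, l)
    sprintf("%.*e %d %d %d %d", digits, v, i, j, k, l)
  writeLines(c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=0,", n, ints$n_electrons),
               sprintf("  ORBSYM=%s", paste(rep("1,", n), collapse = "")),
               "  ISYM=1,", " &END"), con)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    pq <- p * (p - 1L) / 2L + q
    for (r in seq_len(p)) for (s in seq_len(r)) {
      rs <- r * (r - 1L) / 2L + s
      if (rs > pq) next
      v <- ints$g[p, q, r, s]
      if (v != 0) writeLines(fmt(v, p, q, r, s), con)
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    v <- ints$h[p, q]
    if (v != 0) writeLines(fmt(v, p, q, 0L, 0L), con)
  }
  if (write_energies) {
    eps <- c(spaces$eps_occ, spaces$eps_virt)
    for (p in seq_len(n)) writeLines(fmt(eps[p], p, 0L, 0L, 0L), con)
  }
  writeLines(fmt(ints$e_core, 0L, 0L, 0L, 0L), con)
  invisible(path)
}

#' Count symmetry-unique nonzero two-electron elements
#'
#' Brute-force enumeration of unique index quadruples (used to validate the
#' writer's record count).
#' @param g chemist-convention ERI tensor.
#' @export
count_unique_eri <- function(g) {
  n <- dim(g)[1]; cnt <- 0L
  for (p in seq_len(n)) for (q in seq_len(p)) {
    pq <- p * (p - 1L) / 2L + q
    for (r in seq_len(p)) for (s in seq_len(r)) {
      rs <- r * (r - 1L) / 2L + s
      if (rs > pq) next
      if (g[p, q, r, s] != 0) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Import a Hamiltonian from an electronic-structure backend
#'
#' Adapter for a pluggable backend that supplies MO-basis quantities for a
#' real molecule: orbital energies, the one-electron matrix, three-center
#' integrals (pq|P) with the two-center metric V_PQ for a named auxiliary
#' basis, the electron count and the frozen-core count.  The density-fitted
#' two-electron integrals are reconstructed from the factors, and the frozen
#' core is folded in before the correlated spaces are returned.
#'
#' @param provider list with elements \code{eps} (orbital energies, hartree,
#'   ascending), \code{h} (one-electron matrix), \code{three_center}
#'   ((pq|P) array), \code{metric} (V_PQ), \code{n_electrons},
#'   \code{n_frozen_core} (default 0).
#' @return list with \code{spaces}, \code{ints} (density-fitted integrals)
#'   and \code{df} (the fitting factors for the active space).
#' @export
backend_import <- function(provider) {
  need <- c("eps", "h", "three_center", "metric", "n_electrons")
  miss <- setdiff(need, names(provider))
  if (length(miss)) stop("backend provider lacks: ", paste(miss, collapse = ", "))
  df_full <- build_df_factors(provider$three_center, provider$metric)
  g <- df_reconstruct(df_full)
  ints <- mo_integrals(provider$h, g, provider$n_electrons)
  n_occ <- provider$n_electrons %/% 2L
  n <- ints$n_mo
  spaces <- orbital_spaces(n_occ, n - n_occ,
                           eps_occ = provider$eps[seq_len(n_occ)],
                           eps_virt = provider$eps[(n_occ + 1L):n])
  nfc <- provider$n_frozen_core
  if (is.null(nfc)) nfc <- 0L
  if (nfc > 0L) {
    fc <- select_frozen_core(spaces, ints, nfc)
    spaces <- fc$spaces; ints <- fc$ints
  }
  list(spaces = spaces, ints = ints,
       df = cholesky_factorize(ints, tol = 1e-10))
}
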