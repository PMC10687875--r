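# Minimal einsum-style contraction for dense arrays, built on aperm()
# and BLAS matrix multiplication.  Supports two operands, no repeated
# index within one operand, e.g. ec("mnab,ijmn->ijab", W, tau).

ec <- function(spec, A, B = NULL) {
  parts <- strsplit(spec, "->")[[1]]
  ins <- strsplit(parts[1], ",")[[1]]
  out <- if (length(parts) > 1) strsplit(parts[2], "")[[1]] else character(0)
  ia <- strsplit(ins[1], "")[[1]]
  da <- dim(A); if (is.null(da)) da <- length(A)
  if (length(da) != length(ia)) stop("ec: operand 1 rank mismatch in ", spec)
  if (is.null(B)) {
    # permutation / partial trace free case: only permutation supported
    perm <- match(out, ia)
    if (anyNA(perm) || length(out) != length(ia)) stop("ec: bad single-operand spec ", spec)
    return(aperm(A, perm))
  }
  ib <- strsplit(ins[2], "")[[1]]
  db <- dim(B); if (is.null(db)) db <- length(B)
  if (length(db) != length(ib)) stop("ec: operand 2 rank mismatch in ", spec)
  con <- intersect(ia, ib)
  con <- setdiff(con, out)
  fa <- setdiff(ia, con)          # keep in first-operand order
  fb <- setdiff(ib, con)
  # dimension checks
  for (k in con) {
    if (da[match(k, ia)] != db[match(k, ib)])
      stop("ec: contracted dim mismatch for index ", k, " in ", spec)
  }
  Ap <- aperm(A, match(c(fa, con), ia))
  Bp <- aperm(B, match(c(con, fb), ib))
  dfa <- da[match(fa, ia)]; dcon <- da[match(con, ia)]; dfb <- db[match(fb, ib)]
  M <- matrix(Ap, prod(dfa), prod(dcon)) %*% matrix(Bp, prod(dcon), prod(dfb))
  R <- array(M, c(dfa, dfb))
  if (!setequal(out, c(fa, fb))) stop("ec: output indices do not match free indices in ", spec)
  aperm(R, match(out, c(fa, fb)))
}

# antisymmetrize pairs of indices: P(ij) A = A - A with i,j swapped
asym <- function(A, i, j) A - aperm(A, {p <- seq_along(dim(A)); p[c(i, j)] <- p[c(j, i)]; p})
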