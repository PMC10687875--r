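# One-electron integrals, density-fitting tensors and small linear-algebra
# helpers shared by the SCF and correlation modules.

#' Compute AO integrals for a molecule
#'
#' @param mol molecule object.
#' @param basis basis-set name or basis list.
#' @return list with the shell table, overlap \code{S}, core Hamiltonian
#'   \code{hcore}, multipole matrices \code{mp} (about the origin) and the
#'   nuclear repulsion energy.
#' @export
compute_aoints <- function(mol, basis) {
  shells <- build_shells(mol, basis)
  S <- cpp_overlap(shells)
  T <- cpp_kinetic(shells)
  V <- cpp_nuclear(shells, mol$z, mol$coords_bohr)
  mp <- cpp_multipole(shells, c(0, 0, 0))
  list(shells = shells, S = S, hcore = T + V, mp = mp,
       enuc = nuclear_repulsion(mol), nbf = attr(shells, "nbf"))
}

#' Compute density-fitting tensors
#'
#' Builds the three-center integrals \eqn{(\mu\nu|X)} and the Coulomb
#' metric \eqn{V_{XY}=(X|Y)}, and returns the metric-orthogonalized
#' B-tensor with \eqn{(\mu\nu|\lambda\sigma)=\sum_X B_{\mu\nu X}B_{\lambda\sigma X}}.
#' The metric inverse is applied through its Cholesky factor.
#'
#' @param shells orbital shell table.
#' @param aux_shells auxiliary shell table.
#' @return list with \code{B} (nbf x nbf x naux array), \code{naux},
#'   and the auxiliary atom map.
#' @export
compute_df <- function(shells, aux_shells) {
  I3 <- cpp_eri3c(shells, aux_shells)
  V2 <- cpp_eri2c(aux_shells)
  n <- dim(I3)[1]; nx <- dim(I3)[3]
  U <- tryCatch(chol(V2), error = function(e)
    stop("auxiliary Coulomb metric not positive definite: ", conditionMessage(e)))
  # B = I3 * U^{-1}:  B B^T = I3 V^{-1} I3^T
  Bm <- matrix(I3, n * n, nx) %*% backsolve(U, diag(nx))
  # raw integrals and metric are kept: domain construction restricts the
  # auxiliary set by atom before whitening
  list(B = array(Bm, c(n, n, nx)), I3 = I3, V2 = V2, naux = nx,
       aux_atom = attr(aux_shells, "ao_atom"))
}

# B tensor as matrix (nbf*nbf) x naux
.bmat <- function(df) matrix(df$B, dim(df$B)[1]^2, dim(df$B)[3])

# half-transform B over first two indices: C1' B C2 -> (n1, n2, naux)
df_transform <- function(B, C1, C2) {
  n <- dim(B)[1]; nx <- dim(B)[3]
  m <- matrix(B, n, n * nx)
  h <- crossprod(C1, m)                       # n1 x (n*naux)
  h <- array(h, c(ncol(C1), n, nx))
  h <- aperm(h, c(2, 1, 3))
  h <- matrix(h, n, ncol(C1) * nx)
  out <- crossprod(C2, h)                     # n2 x (n1*naux)
  aperm(array(out, c(ncol(C2), ncol(C1), nx)), c(2, 1, 3))
}

# symmetric orthonormalization helpers
lowdin <- function(S, tol = 0) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > max(tol, 1e-14 * max(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
}

# canonical orthonormalization: returns transformation X with X' S X = I,
# dropping near-null directions below tol
canonical_orth <- function(S, tol = 1e-7) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol
  e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]), sum(keep))
}

# semicanonicalization: rotate orbitals C (AO x k) so that C' F C is
# diagonal; returns rotated orbitals and eigenvalues
#' Semicanonicalize a block of orthonormal orbitals
#'
#' Diagonalizes the given Fock matrix within the span of the supplied
#' orthonormal orbitals; occupied and virtual blocks are passed
#' separately by the callers.
#'
#' @param C AO-basis orbital coefficients (columns orthonormal in the
#'   overlap metric).
#' @param fock AO-basis Fock matrix.
#' @param S AO overlap (used to verify orthonormality).
#' @return list with rotated \code{C}, eigenvalues \code{eps} and the
#'   rotation \code{U} (\code{C_new = C U}).
#' @export
semicanonicalize <- function(C, fock, S = NULL) {
  if (ncol(C) == 0)
    return(list(C = C, eps = numeric(0), U = matrix(0, 0, 0)))
  if (!is.null(S)) {
    dev <- max(abs(crossprod(C, S %*% C) - diag(ncol(C))))
    if (dev > 1e-8) stop("semicanonicalize: orbitals not orthonormal (dev ", signif(dev, 3), ")")
  }
  Fb <- crossprod(C, fock %*% C)
  Fb <- (Fb + t(Fb)) / 2
  e <- eigen(Fb, symmetric = TRUE)
  ord <- order(e$values)
  U <- e$vectors[, ord, drop = FALSE]
  # deterministic sign: largest component positive
  for (k in seq_len(ncol(U))) {
    m <- which.max(abs(U[, k]))
    if (U[m, k] < 0) U[, k] <- -U[, k]
  }
  list(C = C %*% U, eps = e$values[ord], U = U)
}

fix_sign <- function(C) {
  for (k in seq_len(ncol(C))) {
    m <- which.max(abs(C[, k]))
    if (C[m, k] < 0) C[, k] <- -C[, k]
  }
  C
}
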