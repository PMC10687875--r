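# Density-fitted SCF: UHF, ROHF (Guest-Saunders effective Fock) and
# quasi-restricted orbitals from a UHF solution.  All Coulomb/exchange
# builds go through the RI-JK route with the shared B tensor.

.df_jk <- function(df, P_tot, C_occ_list) {
  n <- dim(df$B)[1]; nx <- dim(df$B)[3]
  Bm <- .bmat(df)
  gamma <- crossprod(Bm, as.vector(P_tot))         # naux
  J <- matrix(Bm %*% gamma, n, n)
  K <- lapply(C_occ_list, function(Co) {
    if (is.null(Co) || ncol(Co) == 0) return(matrix(0, n, n))
    H <- df_transform(df$B, Co, diag(n))           # no x n x naux
    Hm <- matrix(aperm(H, c(2, 1, 3)), n, ncol(Co) * nx)
    tcrossprod(Hm)
  })
  list(J = J, K = K)
}

.scf_energy <- function(hcore, Fa, Fb, Pa, Pb, enuc) {
  0.5 * (sum(Pa * (hcore + Fa)) + sum(Pb * (hcore + Fb))) + enuc
}

# DIIS helper
.diis_new <- function(nmax = 8) new.env(parent = emptyenv())
.diis_push <- function(env, F_list, err) {
  if (is.null(env$Fs)) { env$Fs <- list(); env$errs <- list() }
  env$Fs[[length(env$Fs) + 1]] <- F_list
  env$errs[[length(env$errs) + 1]] <- err
  if (length(env$Fs) > 8) { env$Fs <- env$Fs[-1]; env$errs <- env$errs[-1] }
  m <- length(env$Fs)
  if (m < 2) return(F_list)
  Bm <- matrix(0, m + 1, m + 1)
  for (i in 1:m) for (j in 1:m) Bm[i, j] <- sum(env$errs[[i]] * env$errs[[j]])
  Bm[m + 1, 1:m] <- -1; Bm[1:m, m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  c_coef <- tryCatch(solve(Bm, rhs)[1:m], error = function(e) NULL)
  if (is.null(c_coef) || any(!is.finite(c_coef))) {
    env$Fs <- env$Fs[m]; env$errs <- env$errs[m]
    return(F_list)
  }
  out <- F_list
  for (k in seq_along(F_list)) {
    acc <- 0 * F_list[[k]]
    for (i in 1:m) acc <- acc + c_coef[i] * env$Fs[[i]][[k]]
    out[[k]] <- acc
  }
  out
}

.occupy <- function(F, X, nocc) {
  Fo <- crossprod(X, F %*% X)
  Fo <- (Fo + t(Fo)) / 2
  e <- eigen(Fo, symmetric = TRUE)
  ord <- order(e$values)                 # ascending orbital energies
  C <- X %*% e$vectors[, ord, drop = FALSE]
  list(C = C, eps = e$values[ord], Cocc = C[, seq_len(nocc), drop = FALSE])
}

scf_uhf <- function(mol, ints, df, maxiter = 200, conv = 1e-10,
                    guess_mix = 0.2) {
  na <- (mol$nelec + mol$multiplicity - 1L) / 2L
  nb <- mol$nelec - na
  X <- lowdin(ints$S)
  n <- ints$nbf
  ga <- .occupy(ints$hcore, X, na)
  gb <- .occupy(ints$hcore, X, nb)
  Ca <- ga$Cocc; Cb <- gb$Cocc
  # break spin symmetry for open shell UHF by mixing HOMO/LUMO of alpha
  if (na > nb && guess_mix > 0 && na < n) {
    h <- ga$C[, na]; l <- ga$C[, na + 1]
    Ca[, na] <- (h + guess_mix * l) / sqrt(1 + guess_mix^2)
  }
  diis <- .diis_new()
  e_old <- Inf; iters <- list()
  for (it in seq_len(maxiter)) {
    Pa <- tcrossprod(Ca); Pb <- tcrossprod(Cb)
    jk <- .df_jk(df, Pa + Pb, list(Ca, Cb))
    Fa <- ints$hcore + jk$J - jk$K[[1]]
    Fb <- ints$hcore + jk$J - jk$K[[2]]
    E <- .scf_energy(ints$hcore, Fa, Fb, Pa, Pb, ints$enuc)
    erra <- Fa %*% Pa %*% ints$S - ints$S %*% Pa %*% Fa
    errb <- Fb %*% Pb %*% ints$S - ints$S %*% Pb %*% Fb
    err <- rbind(crossprod(X, erra %*% X), crossprod(X, errb %*% X))
    iters[[it]] <- c(E = E, err = max(abs(err)))
    if (abs(E - e_old) < conv && max(abs(err)) < 1e-7) {
      sa <- .occupy(Fa, X, na); sb <- .occupy(Fb, X, nb)
      return(list(E = E, Ca = sa$C, Cb = sb$C, eps_a = sa$eps, eps_b = sb$eps,
                  Fa = Fa, Fb = Fb, na = na, nb = nb, niter = it,
                  log = do.call(rbind, iters)))
    }
    e_old <- E
    Fd <- .diis_push(diis, list(Fa, Fb), err)
    sa <- .occupy(Fd[[1]], X, na); sb <- .occupy(Fd[[2]], X, nb)
    Ca <- sa$Cocc; Cb <- sb$Cocc
  }
  stop("UHF did not converge in ", maxiter, " iterations; last |[F,P]| = ",
       signif(max(abs(err)), 3), "; energy history attached: ",
       paste(utils::tail(vapply(iters, `[`, 0, 1), 3), collapse = " "))
}

# Guest-Saunders effective Fock for ROHF; nc closed, no open (spin-up)
.rohf_feff <- function(Fa, Fb, C, nc, no) {
  n <- ncol(C)
  Fam <- crossprod(C, Fa %*% C)
  Fbm <- crossprod(C, Fb %*% C)
  Fc <- (Fam + Fbm) / 2
  idx_c <- seq_len(nc)
  idx_o <- if (no > 0) nc + seq_len(no) else integer(0)
  idx_v <- setdiff(seq_len(n), c(idx_c, idx_o))
  Feff <- Fc
  if (no > 0) {
    Feff[idx_c, idx_o] <- Fbm[idx_c, idx_o]; Feff[idx_o, idx_c] <- Fbm[idx_o, idx_c]
    Feff[idx_o, idx_v] <- Fam[idx_o, idx_v]; Feff[idx_v, idx_o] <- Fam[idx_v, idx_o]
  }
  (Feff + t(Feff)) / 2
}

scf_rohf <- function(mol, ints, df, maxiter = 200, conv = 1e-10) {
  na <- (mol$nelec + mol$multiplicity - 1L) / 2L
  nb <- mol$nelec - na
  nc <- nb; no <- na - nb
  X <- lowdin(ints$S)
  n <- ints$nbf
  C <- .occupy(ints$hcore, X, na)$C
  diis <- .diis_new()
  e_old <- Inf; iters <- list()
  for (it in seq_len(maxiter)) {
    Ca <- C[, seq_len(na), drop = FALSE]
    Cb <- C[, seq_len(nb), drop = FALSE]
    Pa <- tcrossprod(Ca); Pb <- tcrossprod(Cb)
    jk <- .df_jk(df, Pa + Pb, list(Ca, Cb))
    Fa <- ints$hcore + jk$J - jk$K[[1]]
    Fb <- ints$hcore + jk$J - jk$K[[2]]
    E <- .scf_energy(ints$hcore, Fa, Fb, Pa, Pb, ints$enuc)
    Feff_mo <- .rohf_feff(Fa, Fb, C, nc, no)
    Feff <- ints$S %*% C %*% Feff_mo %*% t(C) %*% ints$S
    Feff <- (Feff + t(Feff)) / 2
    Pt <- Pa + Pb
    err <- crossprod(X, (Feff %*% Pt %*% ints$S - ints$S %*% Pt %*% Feff) %*% X)
    iters[[it]] <- c(E = E, err = max(abs(err)))
    if (abs(E - e_old) < conv && max(abs(err)) < 1e-7)
      return(list(E = E, C = C, Fa = Fa, Fb = Fb, na = na, nb = nb,
                  niter = it, log = do.call(rbind, iters)))
    e_old <- E
    Fd <- .diis_push(diis, list(Feff), err)[[1]]
    C <- .occupy(Fd, X, na)$C
  }
  stop("ROHF did not converge in ", maxiter, " iterations; last |[F,P]| = ",
       signif(max(abs(err)), 3))
}

# quasi-restricted orbitals from a converged UHF solution: natural
# orbitals of the total UHF density, classified by occupation.
.qro_from_uhf <- function(uhf, S) {
  P <- tcrossprod(uhf$Ca[, seq_len(uhf$na), drop = FALSE]) +
       tcrossprod(uhf$Cb[, seq_len(uhf$nb), drop = FALSE])
  # diagonalize SPS in Lowdin basis
  X <- lowdin(S)
  M <- crossprod(X, S %*% P %*% S %*% X)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  C <- X %*% e$vectors[, ord, drop = FALSE]
  occ <- e$values[ord]
  list(C = fix_sign(C), occ = occ)
}

#' Build a restricted open-shell reference determinant
#'
#' Runs a density-fitted SCF and returns a restricted spatial orbital set
#' partitioned into doubly occupied (DOMO), singly occupied (SOMO) and
#' virtual orbitals, with the per-spin Fock matrices of the converged
#' determinant. Mode \code{"rohf"} solves the restricted open-shell SCF
#' directly; mode \code{"uhf_qro"} converges UHF and constructs
#' quasi-restricted orbitals from the UHF natural orbitals.
#'
#' @param mol molecule from [molecule()], [read_xyz()] or [generate_fixture()].
#' @param basis basis-set name (e.g. \code{"sto-3g"}, \code{"6-31g"}).
#' @param mode \code{"rohf"} (default) or \code{"uhf_qro"}.
#' @param frozen_core \code{NULL} for standard element counts, or an
#'   integer vector of orbital indices to freeze.
#' @param aux_beta even-tempered ratio of the auxiliary basis.
#' @return a \code{ReferenceState} object (class \code{lnocc_reference}).
#' @export
build_reference <- function(mol, basis = "sto-3g", mode = c("rohf", "uhf_qro"),
                            frozen_core = NULL, aux_beta = 2.5) {
  mode <- match.arg(mode)
  bs <- if (is.character(basis)) load_basis(basis) else basis
  ints <- compute_aoints(mol, bs)
  aux <- build_shells(mol, autoaux_basis(bs, beta = aux_beta))
  df <- compute_df(ints$shells, aux)
  na <- (mol$nelec + mol$multiplicity - 1L) / 2L
  nb <- mol$nelec - na
  if (mode == "rohf") {
    sol <- scf_rohf(mol, ints, df)
    C <- fix_sign(sol$C)
    E <- sol$E
  } else {
    sol <- scf_uhf(mol, ints, df)
    qro <- .qro_from_uhf(sol, ints$S)
    C <- qro$C
    # rebuild the Fock matrices and the energy of the QRO determinant
    Ca <- C[, seq_len(na), drop = FALSE]
    Cb <- C[, seq_len(nb), drop = FALSE]
    Pa <- tcrossprod(Ca); Pb <- tcrossprod(Cb)
    jk <- .df_jk(df, Pa + Pb, list(Ca, Cb))
    sol$Fa <- ints$hcore + jk$J - jk$K[[1]]
    sol$Fb <- ints$hcore + jk$J - jk$K[[2]]
    E <- .scf_energy(ints$hcore, sol$Fa, sol$Fb, Pa, Pb, ints$enuc)
  }
  domo <- seq_len(nb)
  somo <- if (na > nb) nb + seq_len(na - nb) else integer(0)
  # frozen core: lowest spin-averaged Fock expectation among DOMOs
  nfc <- sum(vapply(mol$z, frozen_core_count, integer(1)))
  if (is.null(frozen_core)) {
    if (nfc > 0) {
      fdiag <- diag(crossprod(C[, domo, drop = FALSE],
                              ((sol$Fa + sol$Fb) / 2) %*% C[, domo, drop = FALSE]))
      frozen_core <- domo[order(fdiag)][seq_len(nfc)]
    } else frozen_core <- integer(0)
  }
  structure(list(mol = mol, basis_name = attr(bs, "name"), ints = ints,
                 df = df, aux_shells = aux,
                 C = C, domo_idx = domo, somo_idx = somo,
                 virt_idx = setdiff(seq_len(ints$nbf), c(domo, somo)),
                 fock_up = sol$Fa, fock_down = sol$Fb,
                 scf_energy = E, frozen_core_idx = sort(frozen_core),
                 na = na, nb = nb, mode = mode, scf_niter = sol$niter),
            class = "lnocc_reference")
}

#' @export
print.lnocc_reference <- function(x, ...) {
  cat("<reference>", x$mode, "E =", sprintf("%.10f", x$scf_energy),
      "Eh;", length(x$domo_idx), "DOMO,", length(x$somo_idx), "SOMO,",
      length(x$frozen_core_idx), "frozen\n")
  invisible(x)
}

# off-diagonal AO Fock per spin (vanishes for a self-consistent
# reference): F^OD = F - S C eps C' S with eps the diagonal of the
# semicanonical MO Fock.
#' Off-diagonal Fock matrix of the reference
#'
#' Back-projects the diagonal (semicanonical) part of each spin Fock
#' matrix and subtracts it from the full Fock matrix in the AO basis.
#' For a self-consistent unrestricted reference this vanishes; for an
#' ROHF-derived unrestricted Fock pair it carries the occupied-virtual
#' couplings that generate the singles contribution of the domain MP2
#' energies.
#'
#' @param ref reference state.
#' @return list with AO matrices \code{up} and \code{down}.
#' @export
build_fock_offdiagonal <- function(ref) {
  S <- ref$ints$S
  n <- ref$ints$nbf
  fod_one <- function(F, nocc) {
    Co <- semicanonicalize(ref$C[, seq_len(nocc), drop = FALSE], F)
    Cv <- semicanonicalize(ref$C[, -seq_len(nocc), drop = FALSE], F)
    C <- cbind(Co$C, Cv$C)
    eps <- c(Co$eps, Cv$eps)
    Fd <- S %*% C %*% (eps * t(C)) %*% S
    F - Fd
  }
  list(up = fod_one(ref$fock_up, ref$na), down = fod_one(ref$fock_down, ref$nb))
}
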