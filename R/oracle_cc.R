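# Canonical CCSD(T) oracle machinery: a full-molecule spin-orbital
# system, a separately transcribed canonical CCSD solver,
# explicit-denominator perturbative triples, and a determinant-basis
# FCI for two-electron systems.  The oracle CCSD implements the same
# published spin-orbital amplitude equations as the domain solver but
# is transcribed and organized independently; formulation-level
# validation comes from the FCI and MP2 anchors in the test-suite.

#' Full-molecule spin-orbital system of a reference
#'
#' Canonical (semicanonical per spin) orbitals over the whole molecule,
#' frozen cores excluded; integrals from the global density fitting.
#'
#' @param ref reference state.
#' @return \code{lnocc_so} system.
#' @export
oracle_so_system <- function(ref) {
  cb <- canonical_spin_bases(ref)
  mk <- function(b, F) {
    list(Boo = df_transform(ref$df$B, b$Cocc, b$Cocc),
         Bov = b$Bov,
         Bvv = df_transform(ref$df$B, b$Cvir, b$Cvir),
         eps_occ = b$eps_occ, eps_vir = b$eps_vir,
         foo = crossprod(b$Cocc, F %*% b$Cocc),
         fov = b$fov,
         fvv = crossprod(b$Cvir, F %*% b$Cvir),
         w = NULL)
  }
  so_system(list(up = mk(cb$up, ref$fock_up), dn = mk(cb$dn, ref$fock_down)))
}

#' Canonical CCSD oracle solver
#'
#' Spin-orbital CCSD with a general Fock matrix, transcribed separately
#' from the domain solver: the effective one- and two-particle
#' intermediates are assembled in a different order and grouping, and
#' the quadratic terms are folded into the residual directly where the
#' domain solver folds them into intermediates.
#'
#' @param sys spin-orbital system.
#' @param conv amplitude-change threshold.
#' @param maxiter iteration cap.
#' @return list with \code{energy}, \code{t1}, \code{t2} (occ-major),
#'   \code{niter}.
#' @export
oracle_ccsd <- function(sys, conv = 1e-9, maxiter = 200) {
  no <- sys$no; nv <- sys$nv
  fov <- sys$f_ov
  go <- sys$f_oo - diag(diag(sys$f_oo), no)
  gv <- sys$f_vv - diag(diag(sys$f_vv), nv)
  D1 <- outer(sys$eps_occ, sys$eps_vir, "-")
  D2 <- outer(outer(sys$eps_occ, sys$eps_occ, "+"),
              outer(sys$eps_vir, sys$eps_vir, "+"), "-")
  oovv <- soV(sys, "oovv"); ooov <- soV(sys, "ooov"); oooo <- soV(sys, "oooo")
  ovov <- soV(sys, "ovov"); ovvv <- soV(sys, "ovvv"); vvvv <- soV(sys, "vvvv")
  ovvo <- soV(sys, "ovvo"); ovoo <- soV(sys, "ovoo"); vvvo <- soV(sys, "vvvo")
  mnej <- -aperm(ooov, c(1, 2, 4, 3))          # <mn||ej>
  amef <- -aperm(ovvv, c(2, 1, 3, 4))          # <am||ef>
  t1 <- fov / D1
  t2 <- oovv / D2
  diis <- .diis_new()
  for (it in seq_len(maxiter)) {
    tt <- asym(ec("ia,jb->ijab", t1, t1), 1, 2)
    tau_t <- t2 + 0.5 * tt
    tau <- t2 + tt
    # one-particle intermediates
    Hme <- fov + ec("nf,mnef->me", t1, oovv)
    Hae <- gv - 0.5 * ec("ma,me->ae", t1, fov) +
      ec("mf,mafe->ae", t1, ovvv) - 0.5 * ec("mnaf,mnef->ae", tau_t, oovv)
    Hmi <- go + 0.5 * ec("ie,me->mi", t1, fov) +
      ec("ne,mnie->mi", t1, ooov) + 0.5 * ec("inef,mnef->mi", tau_t, oovv)
    # two-particle intermediates
    Wmnij <- oooo + asym(ec("je,mnie->mnij", t1, ooov), 3, 4) +
      0.25 * ec("ijef,mnef->mnij", tau, oovv)
    Wabef <- vvvv - asym(ec("mb,amef->abef", t1, amef), 1, 2) +
      0.25 * ec("mnab,mnef->abef", tau, oovv)
    Wmbej <- ovvo + ec("jf,mbef->mbej", t1, ovvv) -
      ec("nb,mnej->mbej", t1, mnej) -
      ec("jnfb,mnef->mbej", 0.5 * t2 + ec("jf,nb->jnfb", t1, t1), oovv)
    # T1
    r1 <- fov + ec("ie,ae->ia", t1, Hae) - ec("ma,mi->ia", t1, Hmi) +
      ec("imae,me->ia", t2, Hme) -
      ec("nf,naif->ia", t1, ovov) -
      0.5 * ec("imef,maef->ia", t2, ovvv) -
      0.5 * ec("mnae,nmei->ia", t2, mnej)
    # T2
    r2 <- oovv +
      asym(ec("ijae,be->ijab", t2, Hae - 0.5 * ec("mb,me->be", t1, Hme)), 3, 4) -
      asym(ec("imab,mj->ijab", t2, Hmi + 0.5 * ec("je,me->mj", t1, Hme)), 1, 2) +
      0.5 * ec("mnab,mnij->ijab", tau, Wmnij) +
      0.5 * ec("ijef,abef->ijab", tau, Wabef) +
      asym(asym(aperm(ec("imae,mbej->iajb", t2, Wmbej), c(1, 3, 2, 4)) -
                aperm(ec("iema,mbej->iajb", ec("ie,ma->iema", t1, t1), ovvo),
                      c(1, 3, 2, 4)), 1, 2), 3, 4) +
      asym(ec("ie,abej->ijab", t1, vvvo), 1, 2) -
      asym(ec("ma,mbij->ijab", t1, ovoo), 3, 4)
    t1n <- r1 / D1
    t2n <- r2 / D2
    dmax <- max(max(abs(t1n - t1)), max(abs(t2n - t2)))
    vec <- c(t1n, t2n); errv <- c(t1n - t1, t2n - t2)
    ext <- .diis_push(diis, list(matrix(vec, ncol = 1)), matrix(errv, ncol = 1))[[1]]
    t1 <- matrix(ext[seq_len(no * nv)], no, nv)
    t2 <- array(ext[-seq_len(no * nv)], c(no, no, nv, nv))
    if (dmax < conv) {
      tau <- t2 + asym(ec("ia,jb->ijab", t1, t1), 1, 2)
      E <- sum(fov * t1) + 0.25 * sum(oovv * tau)
      return(list(energy = E, t1 = t1, t2 = t2, niter = it))
    }
  }
  stop("oracle CCSD did not converge in ", maxiter, " iterations (last step ",
       signif(dmax, 3), ")")
}

#' Explicit-denominator perturbative triples oracle
#'
#' Full (T) over all occupied triples with explicit energy
#' denominators, including the off-diagonal-Fock disconnected term of a
#' semicanonical open-shell reference.
#'
#' @param sys spin-orbital system.
#' @param cc converged CCSD amplitudes (occ-major layout).
#' @return (T) energy in hartree.
#' @export
oracle_triples <- function(sys, cc) {
  cpp_triples_explicit(sys$eps_occ, sys$eps_vir, sys$f_ov,
                       cc$t1, cc$t2,
                       soV(sys, "oovv"), soV(sys, "vovv"), soV(sys, "ovoo"))
}

#' Determinant-basis FCI for two-electron systems
#'
#' Exact diagonalization in the basis of all two-electron determinants
#' of a spin-orbital system; the correlation energy anchors the CCSD
#' solvers (CCSD is exact for two electrons).
#'
#' @param sys spin-orbital system with exactly two occupied spin
#'   orbitals.
#' @return list with \code{E_corr} and the reference electronic energy.
#' @export
fci_two_electron <- function(sys) {
  no <- sys$no; nv <- sys$nv; n <- no + nv
  if (no != 2) stop("two-electron FCI requires exactly 2 occupied spin orbitals")
  # full h and V in the spin-orbital basis
  f_full <- rbind(cbind(sys$f_oo, sys$f_ov), cbind(t(sys$f_ov), sys$f_vv))
  Bfull <- array(0, c(n, n, dim(sys$Boo)[3]))
  Bfull[1:no, 1:no, ] <- sys$Boo
  Bfull[1:no, no + 1:nv, ] <- sys$Bov
  Bfull[no + 1:nv, 1:no, ] <- aperm(sys$Bov, c(2, 1, 3))
  Bfull[no + 1:nv, no + 1:nv, ] <- sys$Bvv
  chem <- function(p, q, r, s) sum(Bfull[p, q, ] * Bfull[r, s, ])
  Vas <- function(p, q, r, s) chem(p, r, q, s) - chem(p, s, q, r)
  h <- f_full
  for (p in 1:n) for (q in 1:n)
    h[p, q] <- f_full[p, q] - sum(vapply(1:no, function(j) Vas(p, j, q, j), 0))
  dets <- t(utils::combn(n, 2))
  nd <- nrow(dets)
  H <- matrix(0, nd, nd)
  for (I in 1:nd) for (J in I:nd) {
    a <- dets[I, ]; b <- dets[J, ]
    common <- intersect(a, b)
    if (length(common) == 2) {
      H[I, J] <- h[a[1], a[1]] + h[a[2], a[2]] + Vas(a[1], a[2], a[1], a[2])
    } else if (length(common) == 1) {
      p <- setdiff(a, common); q <- setdiff(b, common)
      ph <- (-1)^(match(p, a) + match(q, b))
      H[I, J] <- ph * (h[p, q] + Vas(p, common, q, common))
    } else {
      H[I, J] <- Vas(a[1], a[2], b[1], b[2])
    }
    H[J, I] <- H[I, J]
  }
  Eref <- h[1, 1] + h[2, 2] + Vas(1, 2, 1, 2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  list(E_corr = min(ev) - Eref, E_ref_elec = Eref)
}
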