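# Spin-orbital coupled cluster in a local interacting subspace (or any
# per-spin orbital system): integral assembly from per-spin three-center
# tensors, CCSD with a general (non-diagonal) Fock matrix, the
# per-central-LMO energy partition, and the Laplace-transform (T)
# contribution of the central LMO.

#' Assemble a spin-orbital system from per-spin bases
#'
#' @param spins list with \code{up}/\code{dn}, each carrying
#'   \code{Boo}, \code{Bov}, \code{Bvv} (auxiliary index last),
#'   \code{eps_occ}, \code{eps_vir}, \code{foo}, \code{fov}, \code{fvv},
#'   and optionally the central image \code{w}.
#' @return \code{lnocc_so} system with cached antisymmetrized integral
#'   blocks, the spin-orbital Fock matrix, and index maps.
#' @export
so_system <- function(spins) {
  nou <- length(spins$up$eps_occ); nod <- length(spins$dn$eps_occ)
  nvu <- length(spins$up$eps_vir); nvd <- length(spins$dn$eps_vir)
  no <- nou + nod; nv <- nvu + nvd
  nx <- dim(spins$up$Boo)[3]
  o_up <- seq_len(nou); o_dn <- nou + seq_len(nod)
  v_up <- seq_len(nvu); v_dn <- nvu + seq_len(nvd)
  fill <- function(d1, d2, up, dn, i_up1, i_up2, i_dn1, i_dn2) {
    A <- array(0, c(d1, d2, nx))
    A[i_up1, i_up2, ] <- up
    A[i_dn1, i_dn2, ] <- dn
    A
  }
  Boo <- fill(no, no, spins$up$Boo, spins$dn$Boo, o_up, o_up, o_dn, o_dn)
  Bov <- fill(no, nv, spins$up$Bov, spins$dn$Bov, o_up, v_up, o_dn, v_dn)
  Bvv <- fill(nv, nv, spins$up$Bvv, spins$dn$Bvv, v_up, v_up, v_dn, v_dn)
  f_oo <- matrix(0, no, no); f_ov <- matrix(0, no, nv); f_vv <- matrix(0, nv, nv)
  f_oo[o_up, o_up] <- spins$up$foo; f_oo[o_dn, o_dn] <- spins$dn$foo
  f_ov[o_up, v_up] <- spins$up$fov; f_ov[o_dn, v_dn] <- spins$dn$fov
  f_vv[v_up, v_up] <- spins$up$fvv; f_vv[v_dn, v_dn] <- spins$dn$fvv
  env <- new.env(parent = emptyenv())
  getB <- function(c1, c2) {
    if (c1 == "o" && c2 == "o") Boo
    else if (c1 == "o" && c2 == "v") Bov
    else if (c1 == "v" && c2 == "o") aperm(Bov, c(2, 1, 3))
    else Bvv
  }
  sys <- list(no = no, nv = nv, nou = nou, nod = nod, nvu = nvu, nvd = nvd,
              o_up = o_up, o_dn = o_dn, v_up = v_up, v_dn = v_dn,
              f_oo = f_oo, f_ov = f_ov, f_vv = f_vv,
              eps_occ = diag(f_oo), eps_vir = diag(f_vv),
              w_up = spins$up$w, w_dn = spins$dn$w,
              Boo = Boo, Bov = Bov, Bvv = Bvv, cache = env)
  class(sys) <- "lnocc_so"
  sys
}

# antisymmetrized integral block <c1 c2 || c3 c4> with caching
soV <- function(sys, key) {
  if (!is.null(sys$cache[[key]])) return(sys$cache[[key]])
  cs <- strsplit(key, "")[[1]]
  getB <- function(c1, c2) {
    if (c1 == "o" && c2 == "o") sys$Boo
    else if (c1 == "o" && c2 == "v") sys$Bov
    else if (c1 == "v" && c2 == "o") aperm(sys$Bov, c(2, 1, 3))
    else sys$Bvv
  }
  t1 <- ec("prx,qsx->pqrs", getB(cs[1], cs[3]), getB(cs[2], cs[4]))
  t2 <- ec("psx,qrx->pqrs", getB(cs[1], cs[4]), getB(cs[2], cs[3]))
  V <- t1 - t2
  sys$cache[[key]] <- V
  V
}

#' Solve the spin-orbital CCSD equations
#'
#' DIIS-accelerated iteration with a general Fock matrix: off-diagonal
#' occupied-occupied and virtual-virtual couplings enter the residuals,
#' occupied-virtual blocks drive the singles. Converges the amplitude
#' residual max-norm below \code{conv}.
#'
#' @param sys spin-orbital system from [so_system()].
#' @param conv residual max-norm threshold.
#' @param maxiter iteration cap.
#' @param diis_n DIIS subspace size.
#' @return list with \code{t1}, \code{t2}, \code{energy} (correlation),
#'   \code{niter}, \code{resid} history.
#' @export
ccsd_solve <- function(sys, conv = 1e-8, maxiter = 100, diis_n = 6) {
  no <- sys$no; nv <- sys$nv
  if (no == 0 || nv == 0)
    return(list(t1 = matrix(0, no, nv),
                t2 = array(0, c(no, no, nv, nv)), energy = 0, niter = 0L,
                resid = numeric(0)))
  f_ov <- sys$f_ov
  D1 <- outer(sys$eps_occ, sys$eps_vir, "-")
  D2 <- outer(sys$eps_occ, sys$eps_occ, "+")
  D2 <- outer(D2, outer(sys$eps_vir, sys$eps_vir, "+"), "-")  # (i,j,a,b)
  Voovv <- soV(sys, "oovv")
  t1 <- f_ov / D1
  t2 <- Voovv / D2
  fods_vv <- sys$f_vv - diag(diag(sys$f_vv), nv)
  fods_oo <- sys$f_oo - diag(diag(sys$f_oo), no)
  Vooov <- soV(sys, "ooov"); Voooo <- soV(sys, "oooo")
  Vovov <- soV(sys, "ovov"); Vovvv <- soV(sys, "ovvv")
  Vvvvv <- soV(sys, "vvvv"); Vovvo <- soV(sys, "ovvo")
  Vovoo <- soV(sys, "ovoo"); Vvvvo <- soV(sys, "vvvo")
  diis_t <- .diis_new()
  resid <- numeric(0)
  for (it in seq_len(maxiter)) {
    tau_t <- t2 + 0.5 * asym(ec("ia,jb->ijab", t1, t1), 1, 2)
    tau <- t2 + asym(ec("ia,jb->ijab", t1, t1), 1, 2)
    Fae <- fods_vv - 0.5 * ec("me,ma->ae", f_ov, t1) +
      ec("mf,mafe->ae", t1, Vovvv) - 0.5 * ec("mnaf,mnef->ae", tau_t, Voovv)
    Fmi <- fods_oo + 0.5 * ec("ie,me->mi", t1, f_ov) +
      ec("ne,mnie->mi", t1, Vooov) + 0.5 * ec("inef,mnef->mi", tau_t, Voovv)
    Fme <- f_ov + ec("nf,mnef->me", t1, Voovv)
    Wmnij <- Voooo + asym(ec("je,mnie->mnij", t1, Vooov), 3, 4) +
      0.25 * ec("ijef,mnef->mnij", tau, Voovv)
    Wabef <- Vvvvv - asym(ec("mb,amef->abef", t1, aperm(Vovvv, c(2, 1, 3, 4)) * -1), 1, 2) +
      0.25 * ec("mnab,mnef->abef", tau, Voovv)
    Wmbej <- Vovvo + ec("jf,mbef->mbej", t1, Vovvv) -
      ec("nb,mnej->mbej", t1, aperm(Vooov, c(1, 2, 4, 3)) * -1) -
      ec("jnfb,mnef->mbej", 0.5 * t2 + ec("jf,nb->jnfb", t1, t1), Voovv)
    # T1 residual (equation form: t1*D1 = rhs)
    rhs1 <- f_ov + ec("ie,ae->ia", t1, Fae) - ec("ma,mi->ia", t1, Fmi) +
      ec("imae,me->ia", t2, Fme) - ec("nf,naif->ia", t1, Vovov) -
      0.5 * ec("imef,maef->ia", t2, Vovvv) -
      0.5 * ec("mnae,nmei->ia", t2, aperm(Vooov, c(1, 2, 4, 3)) * -1)
    # T2 residual
    P_ab1 <- ec("ijae,be->ijab", t2, Fae - 0.5 * ec("mb,me->be", t1, Fme))
    P_ij1 <- ec("imab,mj->ijab", t2, Fmi + 0.5 * ec("je,me->mj", t1, Fme))
    rhs2 <- Voovv + asym(P_ab1, 3, 4) - asym(P_ij1, 1, 2) +
      0.5 * ec("mnab,mnij->ijab", tau, Wmnij) +
      0.5 * ec("ijef,abef->ijab", tau, Wabef)
    tmp <- ec("imae,mbej->iajb", t2, Wmbej)
    tmp <- aperm(tmp, c(1, 3, 2, 4))                    # i j a b
    t1V <- ec("ie,ma->iema", t1, t1)
    tmp2 <- ec("iema,mbej->iajb", t1V, Vovvo)
    tmp2 <- aperm(tmp2, c(1, 3, 2, 4))
    PP <- tmp - tmp2
    PP <- asym(asym(PP, 1, 2), 3, 4)
    rhs2 <- rhs2 + PP +
      asym(ec("ie,abej->ijab", t1, Vvvvo), 1, 2) -
      asym(ec("ma,mbij->ijab", t1, Vovoo), 3, 4)
    t1n <- rhs1 / D1
    t2n <- rhs2 / D2
    r <- max(max(abs(t1n - t1)), max(abs(t2n - t2)))
    resid <- c(resid, r)
    # DIIS on concatenated amplitudes
    vec <- c(t1n, t2n)
    errv <- c(t1n - t1, t2n - t2)
    ext <- .diis_push(diis_t, list(matrix(vec, ncol = 1)), matrix(errv, ncol = 1))[[1]]
    t1 <- matrix(ext[seq_len(no * nv)], no, nv)
    t2 <- array(ext[-seq_len(no * nv)], c(no, no, nv, nv))
    if (r < conv) {
      E <- sum(f_ov * t1) +
        0.25 * sum(Voovv * (t2 + asym(ec("ia,jb->ijab", t1, t1), 1, 2)))
      return(list(t1 = t1, t2 = t2, energy = E, niter = it, resid = resid))
    }
  }
  stop("CCSD did not converge in ", maxiter, " iterations; residual history: ",
       paste(signif(utils::tail(resid, 5), 3), collapse = " "))
}

#' Per-occupied-orbital CCSD energy matrix
#'
#' Symmetric matrix over occupied spin orbitals whose trace is the CCSD
#' correlation energy; contraction with a central-LMO projector yields
#' that LMO's contribution.
#'
#' @param sys spin-orbital system.
#' @param cc converged amplitudes from [ccsd_solve()].
#' @return symmetric \code{no x no} matrix.
#' @export
ccsd_energy_matrix <- function(sys, cc) {
  Voovv <- soV(sys, "oovv")
  tau <- cc$t2 + asym(ec("ia,jb->ijab", cc$t1, cc$t1), 1, 2)
  M <- 0.25 * ec("ijab,kjab->ik", Voovv, tau) +
    sys$f_ov %*% t(cc$t1)
  (M + t(M)) / 2
}

#' CCSD energy contribution of the central LMO
#'
#' Projects the occupied index of the energy partition onto the central
#' LMO image (both spin components for a doubly occupied central LMO).
#'
#' @param sys spin-orbital system (with central images \code{w_up},
#'   \code{w_dn}).
#' @param cc converged amplitudes.
#' @return contribution in hartree.
#' @export
ccsd_contribution <- function(sys, cc) {
  M <- ccsd_energy_matrix(sys, cc)
  wu <- rep(0, sys$no); wu[sys$o_up] <- sys$w_up
  e <- as.numeric(crossprod(wu, M %*% wu))
  if (!is.null(sys$w_dn)) {
    wd <- rep(0, sys$no); wd[sys$o_dn] <- sys$w_dn
    e <- e + as.numeric(crossprod(wd, M %*% wd))
  }
  e
}

#' Laplace-transform (T) contribution of the central LMO
#'
#' Builds triples amplitudes only for the central occupied index via
#' quadrature-dressed intermediates and accumulates the perturbative
#' triples energy of the central LMO, including the
#' off-diagonal-Fock (semicanonical reference) disconnected term.
#'
#' @param sys spin-orbital system.
#' @param cc converged CCSD amplitudes.
#' @param quad Laplace quadrature covering the triples denominator range.
#' @return energy contribution in hartree.
#' @export
triples_contribution_laplace <- function(sys, cc, quad) {
  Voovv <- soV(sys, "oovv")
  Vvovv <- soV(sys, "vovv")
  Vovoo <- soV(sys, "ovoo")
  mu <- (max(sys$eps_occ) + min(sys$eps_vir)) / 2
  e <- 0
  wu <- rep(0, sys$no); wu[sys$o_up] <- sys$w_up
  e <- e + cpp_triples_central(sys$eps_occ, sys$eps_vir, sys$f_ov,
                               cc$t1, cc$t2, Voovv, Vvovv, Vovoo,
                               wu, quad$t, quad$w, mu)
  if (!is.null(sys$w_dn)) {
    wd <- rep(0, sys$no); wd[sys$o_dn] <- sys$w_dn
    e <- e + cpp_triples_central(sys$eps_occ, sys$eps_vir, sys$f_ov,
                                 cc$t1, cc$t2, Voovv, Vvovv, Vovoo,
                                 wd, quad$t, quad$w, mu)
  }
  e
}

# triples denominator range of a spin-orbital system
triples_range <- function(sys) {
  gap <- min(sys$eps_vir) - max(sys$eps_occ)
  list(x_min = 3 * gap, x_max = 3 * (max(sys$eps_vir) - min(sys$eps_occ)),
       gap = gap)
}
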