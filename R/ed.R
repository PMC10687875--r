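# Extended domains: assembly (GSL orthogonalization, PAO center domain,
# per-spin semicanonical bases), density-fitted integral transformation,
# Laplace MP1 amplitudes and the domain MP2 energy contribution.
# The MP2 evaluator is shared between the extended domain and the
# truncated local interacting subspace (the MP2-level correction is the
# difference of the two).

.gs_orth <- function(M, S) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (j > 1) {
      prev <- M[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, S %*% v)
    }
    M[, j] <- v / sqrt(sum(v * (S %*% v)))
  }
  M
}

# project AO-basis orbitals (columns of C, full molecule) onto the span
# of the AOs in `ao`; returns coefficients in that AO block and the
# completeness of each projection
.project_onto_aos <- function(C, ao, S) {
  Sc <- (S %*% C)[ao, , drop = FALSE]
  L <- solve(S[ao, ao, drop = FALSE], Sc)
  compl <- colSums(Sc * L)
  list(coef = L, completeness = compl)
}

#' Assemble the extended domain of a central LMO
#'
#' The occupied subspace holds the central LMO and its strong pair
#' partners, projected onto the union of their extensive BP atom lists
#' and re-orthogonalized by Gram-Schmidt (central first, then SOMOs in
#' ascending index order) followed by Lowdin orthogonalization of the
#' remaining DOMOs. The virtual subspace holds the PAOs centered on the
#' PAO-center-domain (PCD) atoms, with the ED occupied space projected
#' out; SOMOs are appended to the spin-down virtual space. All spaces
#' are semicanonicalized per spin; auxiliary functions are restricted to
#' PCD atoms and the domain's own Coulomb metric is re-factorized.
#'
#' @param central central LMO index.
#' @param ref,lmos,paos,pairlist upstream objects.
#' @param config threshold configuration from [lnocc_config()].
#' @param spin_free force the spin-averaged Fock path (set by the
#'   domain router for SOMO-free domains).
#' @param fods AO off-diagonal Fock pair from [build_fock_offdiagonal()].
#' @return an \code{lnocc_ed} object.
#' @export
assemble_ed <- function(central, ref, lmos, paos, pairlist, config = lnocc_config(),
                        spin_free = FALSE, fods = NULL) {
  S <- ref$ints$S
  ao_atom <- attr(ref$ints$shells, "ao_atom")
  prs <- pairlist$pairs
  strong <- prs[prs$classification == "strong", , drop = FALSE]
  partners <- sort(unique(c(strong$l[strong$k == central],
                            strong$k[strong$l == central])))
  partners <- setdiff(partners, central)
  somo_p <- partners[lmos$origin[partners] == "SOMO"]
  domo_p <- partners[lmos$origin[partners] == "DOMO"]
  occ_ids <- c(central, somo_p, domo_p)
  is_somo <- lmos$origin[occ_ids] == "SOMO"
  if (spin_free && any(is_somo))
    stop("spin-averaged path requested for a domain containing a SOMO")
  bp_big <- lapply(occ_ids, function(i) bp_atom_list(lmos$C[, i], config$T_EDo, ref)$atoms)
  bp_small <- lapply(occ_ids, function(i) bp_atom_list(lmos$C[, i], config$T_0, ref)$atoms)
  atoms <- sort(Reduce(union, bp_big))
  pcd_atoms <- sort(Reduce(union, bp_small))
  ao <- which(ao_atom %in% atoms)
  Sed <- S[ao, ao, drop = FALSE]
  # occupied projection onto the ED AOs
  pr <- .project_onto_aos(lmos$C[, occ_ids, drop = FALSE], ao, S)
  if (pr$completeness[1] < config$T_EDo - 1e-8)
    stop("extended domain too small: central LMO projection loss ",
         signif(1 - pr$completeness[1], 3))
  Lo <- sweep(pr$coef, 2, sqrt(pr$completeness), "/")
  # GSL: exact set = central + SOMOs (in listed order), Lowdin on DOMOs
  n_exact <- 1L + length(somo_p)
  Oe <- .gs_orth(Lo[, seq_len(n_exact), drop = FALSE], Sed)
  occ_rest <- Oe
  if (length(domo_p) > 0) {
    D <- Lo[, (n_exact + 1):ncol(Lo), drop = FALSE]
    D <- D - Oe %*% crossprod(Oe, Sed %*% D)
    D <- D %*% lowdin(crossprod(D, Sed %*% D))
    occ_rest <- cbind(Oe, D)
  }
  # virtual: PAOs centered on PCD atoms, projected, occupied removed
  pao_idx <- which(paos$center_atom %in% pcd_atoms & !paos$flagged)
  Vp <- .project_onto_aos(paos$C[, pao_idx, drop = FALSE], ao, S)$coef
  Vp <- Vp - occ_rest %*% crossprod(occ_rest, Sed %*% Vp)
  vir_rest <- Vp %*% canonical_orth(crossprod(Vp, Sed %*% Vp), tol = config$orth_tol)
  if (ncol(vir_rest) == 0)
    stop("degenerate extended domain: empty virtual space for LMO ", central)
  # Fock matrices of the domain (possibly spin-averaged)
  fup <- ref$fock_up[ao, ao, drop = FALSE]
  fdn <- ref$fock_down[ao, ao, drop = FALSE]
  if (spin_free) { favg <- (fup + fdn) / 2; fup <- favg; fdn <- favg }
  somo_cols <- which(is_somo)
  dn_cols <- which(!is_somo)
  sc_occ_up <- semicanonicalize(occ_rest, fup, Sed)
  sc_occ_dn <- semicanonicalize(occ_rest[, dn_cols, drop = FALSE], fdn, Sed)
  sc_vir_up <- semicanonicalize(vir_rest, fup, Sed)
  vdn_basis <- cbind(vir_rest, occ_rest[, somo_cols, drop = FALSE])
  sc_vir_dn <- semicanonicalize(vdn_basis, fdn, Sed)
  # DF integrals: auxiliaries on PCD atoms, domain metric re-factorized
  aux_keep <- which(ref$df$aux_atom %in% pcd_atoms)
  I3 <- ref$df$I3[ao, ao, aux_keep, drop = FALSE]
  V2 <- ref$df$V2[aux_keep, aux_keep, drop = FALSE]
  U <- tryCatch(chol(V2), error = function(e)
    stop("PCD-restricted auxiliary metric not positive definite (",
         length(aux_keep), " functions)"))
  nE <- length(ao); nx <- length(aux_keep)
  Bed <- array(matrix(I3, nE * nE, nx) %*% backsolve(U, diag(nx)), c(nE, nE, nx))
  # first transformation: restricted occupied
  m <- matrix(Bed, nE, nE * nx)
  Bo <- array(crossprod(occ_rest, m), c(ncol(occ_rest), nE, nx))
  ctr2 <- function(Bo, C2) {
    d <- dim(Bo)
    h <- aperm(Bo, c(2, 1, 3))                  # nE x nocc x nx
    g <- crossprod(C2, matrix(h, d[2], d[1] * d[3]))
    aperm(array(g, c(ncol(C2), d[1], d[3])), c(2, 1, 3))
  }
  B_oo <- ctr2(Bo, occ_rest)
  B_ov <- ctr2(Bo, vir_rest)
  fod_up <- if (is.null(fods)) matrix(0, nE, nE) else fods$up[ao, ao, drop = FALSE]
  fod_dn <- if (is.null(fods)) matrix(0, nE, nE) else fods$down[ao, ao, drop = FALSE]
  if (spin_free) { fa <- (fod_up + fod_dn) / 2; fod_up <- fa; fod_dn <- fa }
  structure(list(central = central, occ_ids = occ_ids, is_somo = is_somo,
                 atoms = atoms, pcd_atoms = pcd_atoms, ao = ao,
                 occ_rest = occ_rest, vir_rest = vir_rest,
                 somo_cols = somo_cols, dn_cols = dn_cols,
                 sc_occ_up = sc_occ_up, sc_occ_dn = sc_occ_dn,
                 sc_vir_up = sc_vir_up, sc_vir_dn = sc_vir_dn,
                 B_oo = B_oo, B_ov = B_ov,
                 fock_up = fup, fock_down = fdn,
                 fod_up = fod_up, fod_dn = fod_dn,
                 Sed = Sed, spin_free = spin_free,
                 B_ao = Bed, ao_atom_local = ao_atom[ao],
                 naux = nx, config = config),
            class = "lnocc_ed")
}

#' @export
print.lnocc_ed <- function(x, ...) {
  cat("<extended domain> central LMO", x$central, ":", length(x$atoms),
      "atoms,", length(x$ao), "AOs,", ncol(x$occ_rest), "occ,",
      ncol(x$vir_rest), "PAO-virtuals,", x$naux, "aux",
      if (x$spin_free) "(spin-averaged)" else "", "\n")
  invisible(x)
}

# per-spin semicanonical working bases of a domain (ED or LIS level).
# Returns, for each spin, occupied/virtual energies, the
# occupied-virtual B tensor, the central-LMO image in the occupied
# basis, the off-diagonal Fock block, plus bookkeeping.
domain_spin_bases <- function(ed) {
  nocc <- ncol(ed$occ_rest); nvr <- ncol(ed$vir_rest); nx <- ed$naux
  rot <- function(B, Uo, Uv) {
    d <- dim(B)
    h <- crossprod(Uo, matrix(B, d[1], d[2] * d[3]))     # occupied index
    h <- aperm(array(h, c(ncol(Uo), d[2], d[3])), c(2, 1, 3))
    g <- crossprod(Uv, matrix(h, d[2], ncol(Uo) * d[3])) # virtual index
    aperm(array(g, c(ncol(Uv), ncol(Uo), d[3])), c(2, 1, 3))
  }
  # spin-up: occupied = all restricted occ; virtual = PAO-derived set
  Uou <- ed$sc_occ_up$U; Uvu <- ed$sc_vir_up$U
  Bov_up <- rot(ed$B_ov, Uou, Uvu)
  w_up <- Uou[1, ]
  fod_up <- crossprod(ed$sc_occ_up$C, ed$fod_up %*% ed$sc_vir_up$C)
  # spin-down: occupied = DOMO-type columns; virtual = [PAO set, SOMOs]
  nso <- length(ed$somo_cols)
  Bdn_raw <- array(0, c(length(ed$dn_cols), nvr + nso, nx))
  Bdn_raw[, seq_len(nvr), ] <- ed$B_ov[ed$dn_cols, , , drop = FALSE]
  if (nso > 0)
    Bdn_raw[, nvr + seq_len(nso), ] <- ed$B_oo[ed$dn_cols, ed$somo_cols, , drop = FALSE]
  Uod <- ed$sc_occ_dn$U; Uvd <- ed$sc_vir_dn$U
  Bov_dn <- rot(Bdn_raw, Uod, Uvd)
  cpos_dn <- match(1L, ed$dn_cols)
  w_dn <- if (!is.na(cpos_dn)) Uod[cpos_dn, ] else NULL
  fod_dn <- crossprod(ed$sc_occ_dn$C, ed$fod_dn %*% ed$sc_vir_dn$C)
  list(up = list(eps_occ = ed$sc_occ_up$eps, eps_vir = ed$sc_vir_up$eps,
                 Bov = Bov_up, w = w_up, fod = fod_up),
       dn = list(eps_occ = ed$sc_occ_dn$eps, eps_vir = ed$sc_vir_dn$eps,
                 Bov = Bov_dn, w = w_dn, fod = fod_dn))
}

# Laplace quadrature for a domain: pooled denominator range over both
# spins, covering singles (1-body) and doubles (2-body) gaps
domain_quadrature <- function(sb, T_LT) {
  eo <- c(sb$up$eps_occ, sb$dn$eps_occ)
  ev <- c(sb$up$eps_vir, sb$dn$eps_vir)
  gap1 <- min(ev) - max(eo)
  x_max <- 2 * (max(ev) - min(eo))
  if (gap1 <= 0)
    stop("non-positive occupied-virtual gap (", signif(gap1, 4),
         " Eh): near-degenerate domain")
  laplace_quadrature_cached(gap1, x_max, T_LT)
}

# MP1 amplitudes for the fixed central occupied index, one spin case.
# sc: central-spin basis; sp: partner-spin basis; returns array
# t[j, a, b] with a in the central spin's virtuals, b in the partner's.
.mp1_case <- function(sc, sp, quad, mu, antisym) {
  nv_c <- length(sc$eps_vir); nv_p <- length(sp$eps_vir)
  no_p <- length(sp$eps_occ); nx <- dim(sc$Bov)[3]
  Tt <- array(0, c(no_p, nv_c, nv_p))
  for (q in seq_along(quad$t)) {
    tq <- quad$t[q]
    do_c <- exp((sc$eps_occ - mu) * tq)
    dv_c <- exp(-(sc$eps_vir - mu) * tq)
    do_p <- exp((sp$eps_occ - mu) * tq)
    dv_p <- exp(-(sp$eps_vir - mu) * tq)
    # central row, dressed
    wce <- sc$w * do_c
    Bc <- matrix(crossprod(wce, matrix(sc$Bov, length(sc$eps_occ), nv_c * nx)),
                 nv_c, nx) * dv_c
    Bd <- sp$Bov * rep(do_p, times = nv_p * nx)
    Bd <- Bd * rep(rep(dv_p, each = no_p), times = nx)
    Tq <- matrix(Bd, no_p * nv_p, nx) %*% t(Bc)    # (j b) x a
    Tt <- Tt - quad$w[q] * aperm(array(Tq, c(no_p, nv_p, nv_c)), c(1, 3, 2))
  }
  if (antisym) Tt - aperm(Tt, c(1, 3, 2)) else Tt
}

# undressed integrals with the central projected on the occupied index:
# g[j, a, b] = (c a | j b)
.g_case <- function(sc, sp) {
  nv_c <- length(sc$eps_vir); nv_p <- length(sp$eps_vir)
  no_p <- length(sp$eps_occ); nx <- dim(sc$Bov)[3]
  Bc <- matrix(crossprod(sc$w, matrix(sc$Bov, length(sc$eps_occ), nv_c * nx)),
               nv_c, nx)
  Tq <- matrix(sp$Bov, no_p * nv_p, nx) %*% t(Bc)
  aperm(array(Tq, c(no_p, nv_p, nv_c)), c(1, 3, 2))
}

# Laplace singles energy of the central LMO from the off-diagonal Fock
.singles_case <- function(sb1, quad, mu) {
  e <- 0
  for (q in seq_along(quad$t)) {
    tq <- quad$t[q]
    v <- as.vector(crossprod(sb1$w * exp((sb1$eps_occ - mu) * tq / 2), sb1$fod)) *
      exp(-(sb1$eps_vir - mu) * tq / 2)
    e <- e - quad$w[q] * sum(v * v)
  }
  e
}

#' Domain MP2 energy contribution of the central LMO
#'
#' Evaluates the MP2 doubles contribution of the central LMO (both spin
#' components for a doubly occupied central, one for a singly occupied
#' one) from Laplace-factorized MP1 amplitudes, plus the singles
#' contribution generated by the off-diagonal Fock matrix (the only
#' singles kept; truncation-induced singles are discarded).
#'
#' @param sb spin bases from \code{domain_spin_bases}.
#' @param quad Laplace quadrature from \code{domain_quadrature}.
#' @param keep_amplitudes also return the MP1 amplitude blocks (needed
#'   for LNO construction).
#' @return list with \code{energy}, \code{doubles}, \code{singles} and
#'   optionally \code{amps}.
#' @export
domain_mp2 <- function(sb, quad, keep_amplitudes = FALSE) {
  mu <- (max(c(sb$up$eps_occ, sb$dn$eps_occ)) +
         min(c(sb$up$eps_vir, sb$dn$eps_vir))) / 2
  has_dn <- !is.null(sb$dn$w)
  t_uu <- .mp1_case(sb$up, sb$up, quad, mu, antisym = TRUE)
  t_ud <- .mp1_case(sb$up, sb$dn, quad, mu, antisym = FALSE)
  g_uu <- .g_case(sb$up, sb$up); g_uu <- g_uu - aperm(g_uu, c(1, 3, 2))
  g_ud <- .g_case(sb$up, sb$dn)
  e_d <- 0.25 * sum(t_uu * g_uu) + 0.5 * sum(t_ud * g_ud)
  e_s <- .singles_case(sb$up, quad, mu)
  t_dd <- NULL; t_du <- NULL
  if (has_dn) {
    t_dd <- .mp1_case(sb$dn, sb$dn, quad, mu, antisym = TRUE)
    t_du <- .mp1_case(sb$dn, sb$up, quad, mu, antisym = FALSE)
    g_dd <- .g_case(sb$dn, sb$dn); g_dd <- g_dd - aperm(g_dd, c(1, 3, 2))
    g_du <- .g_case(sb$dn, sb$up)
    e_d <- e_d + 0.25 * sum(t_dd * g_dd) + 0.5 * sum(t_du * g_du)
    e_s <- e_s + .singles_case(sb$dn, quad, mu)
  }
  out <- list(energy = e_d + e_s, doubles = e_d, singles = e_s)
  if (keep_amplitudes)
    out$amps <- list(uu = t_uu, ud = t_ud, dd = t_dd, du = t_du, mu = mu)
  out
}

#' MP2 energy contribution of a central LMO in its extended domain
#'
#' @param ed extended domain.
#' @param quad optional pre-built quadrature.
#' @param keep_amplitudes keep MP1 amplitudes for LNO construction.
#' @return as [domain_mp2()], plus the spin bases and quadrature.
#' @export
ed_mp2_energy <- function(ed, quad = NULL, keep_amplitudes = FALSE) {
  sb <- domain_spin_bases(ed)
  if (is.null(quad)) quad <- domain_quadrature(sb, ed$config$T_LT)
  res <- domain_mp2(sb, quad, keep_amplitudes = keep_amplitudes)
  res$spin_bases <- sb
  res$quad <- quad
  res
}
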