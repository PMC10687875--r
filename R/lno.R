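# Local natural orbitals: MP1 density-matrix fragments of the central
# LMO, restricted LNO construction with SOMO-block zeroing and the
# factor-2 scaling for singly occupied central LMOs, occupation-number
# truncation, and assembly of the local interacting subspace (LIS).

#' Occupied MP1 density fragment of the central LMO
#'
#' Builds the per-spin occupied-occupied second-order density blocks
#' from the central LMO's MP1 amplitudes, transforms them to the
#' restricted occupied basis of the ED and sums the spins. The central
#' row/column and any SOMO-DOMO coupling blocks are zeroed so that
#' diagonalization cannot mix them; for a singly occupied central LMO
#' the fragment is scaled by 2 (the spin-down amplitude terms vanish
#' identically).
#'
#' @param ed extended domain.
#' @param amps MP1 amplitude blocks from [ed_mp2_energy()] with
#'   \code{keep_amplitudes = TRUE}.
#' @return list with the zeroed restricted matrix \code{D}, the raw
#'   (unzeroed) matrix \code{D_raw} and the \code{scale} applied.
#' @export
occupied_density_fragment <- function(ed, amps) {
  nocc <- ncol(ed$occ_rest)
  ctr_jk <- function(t) {
    d <- dim(t)
    m <- matrix(t, d[1], d[2] * d[3])
    tcrossprod(m)
  }
  # spin-up block: partner occupied index is spin-up
  D_up <- 0.5 * ctr_jk(amps$uu)
  if (!is.null(amps$du)) D_up <- D_up + ctr_jk(amps$du)
  # spin-down block: partner occupied index is spin-down
  D_dn <- 0.5 * (if (!is.null(amps$dd)) ctr_jk(amps$dd) else
                   matrix(0, length(ed$dn_cols), length(ed$dn_cols)))
  D_dn <- D_dn + ctr_jk(amps$ud)
  Uou <- ed$sc_occ_up$U; Uod <- ed$sc_occ_dn$U
  D <- Uou %*% D_up %*% t(Uou)
  Dd <- Uod %*% D_dn %*% t(Uod)
  D[ed$dn_cols, ed$dn_cols] <- D[ed$dn_cols, ed$dn_cols] + Dd
  scale <- if (ed$is_somo[1]) 2 else 1
  D <- scale * D
  D_raw <- D
  D[1, ] <- 0; D[, 1] <- 0
  if (length(ed$somo_cols) > 0) {
    oth <- setdiff(seq_len(nocc), ed$somo_cols)
    D[ed$somo_cols, oth] <- 0
    D[oth, ed$somo_cols] <- 0
  }
  list(D = (D + t(D)) / 2, D_raw = D_raw, scale = scale)
}

#' Virtual MP1 density fragment of the central LMO
#'
#' The free occupied index of the MP1 amplitudes is first transformed
#' to the retained occupied LNO basis; each spin's virtual-virtual
#' block then collects the contributions of every amplitude block with
#' a virtual index of that spin. Blocks are transformed to the
#' restricted PAO-derived basis, spin-summed, SOMO-virtual couplings
#' zeroed, and scaled by 2 for a singly occupied central LMO.
#'
#' @param ed extended domain.
#' @param amps MP1 amplitudes.
#' @param kept_occ occupied-LNO selection from [select_occupied_lnos()].
#' @return list with zeroed restricted matrix \code{D} (PAO block) and
#'   the scale.
#' @export
virtual_density_fragment <- function(ed, amps, kept_occ) {
  nvr <- ncol(ed$vir_rest); nso <- length(ed$somo_cols)
  P_up <- kept_occ$P_up      # ED sc-up occupied -> retained LNO basis
  P_dn <- kept_occ$P_dn
  tr_occ <- function(t, P) {
    d <- dim(t)
    out <- crossprod(P, matrix(t, d[1], d[2] * d[3]))
    array(out, c(ncol(P), d[2], d[3]))
  }
  # contract over the partner occupied (retained) and the other virtual
  ctr_ab <- function(t, which_vir) {
    d <- dim(t)
    if (which_vir == 2) {
      m <- matrix(aperm(t, c(2, 1, 3)), d[2], d[1] * d[3])
    } else {
      m <- matrix(aperm(t, c(3, 1, 2)), d[3], d[1] * d[2])
    }
    tcrossprod(m)
  }
  t_uu <- tr_occ(amps$uu, P_up)
  t_ud <- tr_occ(amps$ud, P_dn)
  D_up <- 0.5 * ctr_ab(t_uu, 2) + ctr_ab(t_ud, 2)
  D_dn_dim <- length(ed$sc_vir_dn$eps)
  D_dn <- ctr_ab(t_ud, 3)
  if (!is.null(amps$dd)) {
    t_dd <- tr_occ(amps$dd, P_dn)
    t_du <- tr_occ(amps$du, P_up)
    D_dn <- D_dn + 0.5 * ctr_ab(t_dd, 2) + ctr_ab(t_du, 2)
    D_up <- D_up + ctr_ab(t_du, 3)
  }
  Wu <- ed$sc_vir_up$U; Wd <- ed$sc_vir_dn$U
  Dr <- Wu %*% D_up %*% t(Wu)
  Dfull <- Wd %*% D_dn %*% t(Wd)        # (nvr+nso) square
  Dr <- Dr + Dfull[seq_len(nvr), seq_len(nvr), drop = FALSE]
  scale <- if (ed$is_somo[1]) 2 else 1
  list(D = scale * (Dr + t(Dr)) / 2, scale = scale)
}

#' Select occupied LNOs
#'
#' Diagonalizes the zeroed occupied fragment in the truncatable DOMO
#' block and keeps eigenvectors with occupation above \code{eps_o}
#' (with a 1e-12 degeneracy grace); the central LMO and all SOMOs are
#' kept unconditionally.
#'
#' @param ed extended domain.
#' @param occ_frag fragment from [occupied_density_fragment()].
#' @param eps_o occupied LNO threshold.
#' @return list with the restricted-basis selector \code{K}
#'   (occupied columns of the LIS in the ED restricted occupied basis),
#'   per-spin semicanonical-to-retained maps \code{P_up}, \code{P_dn},
#'   and the occupation spectrum.
#' @export
select_occupied_lnos <- function(ed, occ_frag, eps_o) {
  nocc <- ncol(ed$occ_rest)
  fixed <- c(1L, ed$somo_cols)
  fixed <- unique(fixed)
  tr_block <- setdiff(seq_len(nocc), fixed)
  occs <- numeric(0); Kt <- NULL
  if (length(tr_block) > 0) {
    Db <- occ_frag$D[tr_block, tr_block, drop = FALSE]
    e <- eigen(Db, symmetric = TRUE)
    ord <- order(e$values, decreasing = TRUE)
    vals <- e$values[ord]; vecs <- e$vectors[, ord, drop = FALSE]
    keep <- vals > eps_o - 1e-12
    occs <- vals
    if (any(keep)) {
      Kt <- matrix(0, nocc, sum(keep))
      Kt[tr_block, ] <- vecs[, keep, drop = FALSE]
    }
  }
  K <- cbind(diag(nocc)[, fixed, drop = FALSE], Kt)
  # per-spin maps: ED semicanonical occupied -> retained columns
  P_up <- crossprod(ed$sc_occ_up$U, K)
  K_dn <- K[ed$dn_cols, , drop = FALSE]
  dn_keep <- colSums(abs(K_dn)) > 1e-12        # SOMO columns vanish for spin-down
  P_dn <- crossprod(ed$sc_occ_dn$U, K_dn[, dn_keep, drop = FALSE])
  list(K = K, P_up = P_up, P_dn = P_dn, dn_keep = dn_keep,
       occupations = occs, n_kept = ncol(K),
       fixed = fixed, fixed_is_somo = fixed %in% ed$somo_cols)
}

#' Build the local interacting subspace of a domain
#'
#' Runs the LNO selection (occupied, then virtual with the occupied
#' restriction applied) and assembles a domain object over the retained
#' spaces, structurally identical to the extended domain so that the
#' same MP2/CC machinery applies.
#'
#' @param ed extended domain.
#' @param mp2 result of [ed_mp2_energy()] with amplitudes kept.
#' @param eps_o,eps_v LNO occupation thresholds.
#' @return \code{lnocc_lis} object (an \code{lnocc_ed} over the LIS
#'   bases, with occupation spectra attached).
#' @export
build_lis <- function(ed, mp2, eps_o = 1e-5, eps_v = 1e-6) {
  of <- occupied_density_fragment(ed, mp2$amps)
  ko <- select_occupied_lnos(ed, of, eps_o)
  vf <- virtual_density_fragment(ed, mp2$amps, ko)
  ev <- eigen(vf$D, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)
  vals <- ev$values[ord]; vecs <- ev$vectors[, ord, drop = FALSE]
  keepv <- vals > eps_v - 1e-12
  if (!any(keepv) && length(ed$somo_cols) == 0)
    stop("no virtual LNO above threshold ", eps_v, "; occupation spectrum: ",
         paste(signif(utils::head(vals, 5), 3), collapse = " "))
  Vk <- vecs[, keepv, drop = FALSE]
  occ_rest <- ed$occ_rest %*% ko$K
  vir_rest <- ed$vir_rest %*% Vk
  # retained columns: [central, SOMOs, kept DOMO-LNOs]; the central may
  # itself be the (or a) SOMO
  is_somo <- c(ko$fixed_is_somo, rep(FALSE, ncol(occ_rest) - length(ko$fixed)))
  somo_cols <- which(is_somo)
  dn_cols <- which(!is_somo)
  Sed <- ed$Sed
  sc_occ_up <- semicanonicalize(occ_rest, ed$fock_up, Sed)
  sc_occ_dn <- semicanonicalize(occ_rest[, dn_cols, drop = FALSE], ed$fock_down, Sed)
  sc_vir_up <- semicanonicalize(vir_rest, ed$fock_up, Sed)
  vdn_basis <- cbind(vir_rest, occ_rest[, somo_cols, drop = FALSE])
  sc_vir_dn <- semicanonicalize(vdn_basis, ed$fock_down, Sed)
  # LIS three-center tensors from the ED ones
  tr2 <- function(B, C1, C2) {
    d <- dim(B)
    h <- crossprod(C1, matrix(B, d[1], d[2] * d[3]))
    h <- aperm(array(h, c(ncol(C1), d[2], d[3])), c(2, 1, 3))
    g <- crossprod(C2, matrix(h, d[2], ncol(C1) * d[3]))
    aperm(array(g, c(ncol(C2), ncol(C1), d[3])), c(2, 1, 3))
  }
  B_oo <- tr2(ed$B_oo, ko$K, ko$K)
  B_ov <- tr2(ed$B_ov, ko$K, Vk)
  structure(list(central = ed$central, occ_ids = ed$occ_ids[ko$fixed],
                 is_somo = is_somo,
                 atoms = ed$atoms, pcd_atoms = ed$pcd_atoms, ao = ed$ao,
                 occ_rest = occ_rest, vir_rest = vir_rest,
                 somo_cols = somo_cols, dn_cols = dn_cols,
                 sc_occ_up = sc_occ_up, sc_occ_dn = sc_occ_dn,
                 sc_vir_up = sc_vir_up, sc_vir_dn = sc_vir_dn,
                 B_oo = B_oo, B_ov = B_ov,
                 fock_up = ed$fock_up, fock_down = ed$fock_down,
                 fod_up = ed$fod_up, fod_dn = ed$fod_dn,
                 Sed = Sed, spin_free = ed$spin_free,
                 naux = ed$naux, config = ed$config,
                 occ_spectrum = ko$occupations, vir_spectrum = vals,
                 K_occ = ko$K, K_vir = Vk),
            class = c("lnocc_lis", "lnocc_ed"))
}

#' MP2 energy contribution of the central LMO in its LIS
#'
#' Same machinery and off-diagonal-Fock singles convention as
#' [ed_mp2_energy()], evaluated over the truncated LNO spaces; the
#' difference to the ED value corrects the LNO truncation at the MP2
#' level.
#'
#' @param lis LIS object from [build_lis()].
#' @return as [domain_mp2()].
#' @export
lis_mp2_energy <- function(lis) ed_mp2_energy(lis)

#' Export the LNO occupation spectra of a domain
#'
#' @param lis LIS object.
#' @param path CSV output path.
#' @export
write_occupation_spectra <- function(lis, path) {
  occ <- lis$occ_spectrum; vir <- lis$vir_spectrum
  utils::write.csv(data.frame(
    block = c(rep("occupied", length(occ)), rep("virtual", length(vir))),
    index = c(seq_along(occ), seq_along(vir)),
    occupation = c(occ, vir)), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.lnocc_lis <- function(x, ...) {
  cat("<LIS> central LMO", x$central, ":", ncol(x$occ_rest), "occ LNOs,",
      ncol(x$vir_rest), "vir LNOs (+", length(x$somo_cols), "SOMOs),",
      x$naux, "aux\n")
  invisible(x)
}
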