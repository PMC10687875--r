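# Canonical (full-space) density-fitted oracles: semicanonical MP2,
# spin-orbital CCSD with a directly transcribed residual (independent of
# the domain CCSD solver), and explicit-denominator perturbative
# triples.  Used as brute-force references in the tests and the
# acceptance checks; frozen cores are excluded throughout.

# full-molecule semicanonical spin bases of the reference determinant
canonical_spin_bases <- function(ref, fods = NULL) {
  if (is.null(fods)) fods <- build_fock_offdiagonal(ref)
  corr_up <- setdiff(seq_len(ref$na), ref$frozen_core_idx)
  corr_dn <- setdiff(seq_len(ref$nb), ref$frozen_core_idx)
  vir_up <- (ref$na + 1):ref$ints$nbf
  vir_dn <- (ref$nb + 1):ref$ints$nbf
  mk <- function(occ_idx, vir_idx, F, fod) {
    so <- semicanonicalize(ref$C[, occ_idx, drop = FALSE], F)
    sv <- semicanonicalize(ref$C[, vir_idx, drop = FALSE], F)
    list(Cocc = so$C, Cvir = sv$C, eps_occ = so$eps, eps_vir = sv$eps,
         Bov = df_transform(ref$df$B, so$C, sv$C),
         fod = crossprod(so$C, fod %*% sv$C),
         fov = crossprod(so$C, F %*% sv$C))
  }
  list(up = mk(corr_up, vir_up, ref$fock_up, fods$up),
       dn = mk(corr_dn, vir_dn, ref$fock_down, fods$down))
}

#' Canonical DF-MP2 oracle with explicit denominators
#'
#' Semicanonical unrestricted MP2 over the whole molecule (frozen cores
#' excluded), including the singles contribution generated by the
#' off-diagonal Fock matrix of a non-self-consistent (restricted
#' open-shell) reference.
#'
#' @param ref reference state.
#' @return list with \code{E_corr}, components, and a per-spin-orbital
#'   breakdown is intentionally not provided here (see the CCSD oracle).
#' @export
oracle_mp2 <- function(ref) {
  cb <- canonical_spin_bases(ref)
  e_same <- function(b) {
    no <- length(b$eps_occ); nv <- length(b$eps_vir)
    if (no == 0 || nv == 0) return(0)
    G <- matrix(b$Bov, no * nv, dim(b$Bov)[3])
    eri <- array(tcrossprod(G), c(no, nv, no, nv))
    D <- outer(b$eps_occ, b$eps_vir, "-")          # eps_i - eps_a
    Dm <- outer(D, D, "+")                         # (i,a,j,b)
    g_anti <- eri - aperm(eri, c(1, 4, 3, 2))
    0.25 * sum(g_anti^2 / Dm)
  }
  e_mixed <- function(b1, b2) {
    no1 <- length(b1$eps_occ); nv1 <- length(b1$eps_vir)
    no2 <- length(b2$eps_occ); nv2 <- length(b2$eps_vir)
    if (no1 * nv1 * no2 * nv2 == 0) return(0)
    G1 <- matrix(b1$Bov, no1 * nv1, dim(b1$Bov)[3])
    G2 <- matrix(b2$Bov, no2 * nv2, dim(b2$Bov)[3])
    eri <- array(tcrossprod(G1, G2), c(no1, nv1, no2, nv2))
    D1 <- outer(b1$eps_occ, b1$eps_vir, "-")
    D2 <- outer(b2$eps_occ, b2$eps_vir, "-")
    sum(eri^2 / outer(D1, D2, "+"))
  }
  e_singles <- function(b) {
    if (length(b$eps_occ) == 0) return(0)
    sum(b$fod^2 / outer(b$eps_occ, b$eps_vir, "-"))
  }
  doubles <- e_same(cb$up) + e_same(cb$dn) + e_mixed(cb$up, cb$dn)
  singles <- e_singles(cb$up) + e_singles(cb$dn)
  list(E_corr = doubles + singles, doubles = doubles, singles = singles)
}
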