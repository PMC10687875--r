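# Extended domains: assembly invariants, MP1 amplitudes against
# explicit denominators, and the ED MP2 energy against the canonical
# oracle in the no-truncation limit.

ed_setup <- function(ref, key, preset = "none") {
  cfg <- lnocc_config(preset)
  st <- pair_setup(ref, key, cfg)
  memo(paste0("eds_", key, "_", preset), {
    lapply(seq_len(ncol(st$lmos$C)), function(L)
      assemble_ed(L, ref, st$lmos, st$paos, st$pairlist, cfg, fods = st$fods))
  })
}

test_that("ED preserves the central LMO and SOMOs exactly through GSL", {
  ref <- ref_ch3_sto()
  cfg <- lnocc_config("normal")
  st <- pair_setup(ref, "ch3_sto")
  for (L in c(1, which(st$lmos$origin == "SOMO"))) {
    ed <- assemble_ed(L, ref, st$lmos, st$paos, st$pairlist, cfg, fods = st$fods)
    # overlap of the original central LMO with its ED image
    Sfull <- ref$ints$S
    v <- st$lmos$C[, L]
    img <- rep(0, ref$ints$nbf); img[ed$ao] <- ed$occ_rest[, 1]
    ov <- abs(sum(v * (Sfull %*% img)))
    expect_gt(ov, 1 - 1e-6)
    # occupied-virtual orthogonality inside the domain
    dev <- crossprod(ed$occ_rest, ed$Sed %*% ed$vir_rest)
    expect_lt(max(abs(dev)), 1e-8)
    # ED atoms cover the central LMO's extensive BP list
    expect_true(all(bp_atom_list(v, cfg$T_EDo, ref)$atoms %in% ed$atoms))
  }
})

test_that("MP1 amplitudes reproduce explicit denominators in a canonical basis", {
  ref <- ref_water_sto()
  eds <- ed_setup(ref, "water_sto")
  ed <- eds[[1]]
  sb <- domain_spin_bases(ed)
  # make the "central" a genuine semicanonical orbital so that explicit
  # denominators are exact, then compare against the Laplace assembly
  sb$up$w <- c(1, rep(0, length(sb$up$eps_occ) - 1))
  sb$dn$w <- c(1, rep(0, length(sb$dn$eps_occ) - 1))
  quad <- domain_quadrature(sb, 1e-7)
  res <- domain_mp2(sb, quad, keep_amplitudes = TRUE)
  up <- sb$up
  no <- length(up$eps_occ); nv <- length(up$eps_vir); nx <- dim(up$Bov)[3]
  Bc <- matrix(up$Bov[1, , ], nv, nx)
  g <- ec("ax,jbx->jab", Bc, up$Bov)
  D <- up$eps_occ[1] +
    outer(up$eps_occ, outer(up$eps_vir, up$eps_vir, "+"), "-")
  texp <- (g - aperm(g, c(1, 3, 2))) / D
  expect_lt(max(abs(res$amps$uu - texp)), 1e-5)
  # same-spin antisymmetry is exact
  expect_equal(res$amps$uu, -aperm(res$amps$uu, c(1, 3, 2)), tolerance = 1e-12)
})

test_that("summed ED MP2 contributions reproduce canonical MP2 (closed shell)", {
  ref <- ref_water_sto()
  eds <- ed_setup(ref, "water_sto")
  tot <- sum(vapply(eds, function(ed) ed_mp2_energy(ed)$energy, 0))
  om <- memo("omp2_water", oracle_mp2(ref))
  expect_lt(abs(tot - om$E_corr), 1e-8)
})

test_that("summed ED MP2 contributions reproduce canonical MP2 (open shell)", {
  ref <- ref_ch3_sto()
  eds <- ed_setup(ref, "ch3_sto")
  res <- lapply(eds, ed_mp2_energy)
  tot <- sum(vapply(res, `[[`, 0, "energy"))
  om <- memo("omp2_ch3", oracle_mp2(ref))
  expect_lt(abs(tot - om$E_corr), 1e-8)
  # every domain contribution is negative
  expect_true(all(vapply(res, `[[`, 0, "energy") < 0))
  # zero off-diagonal Fock would give zero singles: closed-shell water
  edw <- ed_setup(ref_water_sto(), "water_sto")[[1]]
  expect_lt(abs(ed_mp2_energy(edw)$singles), 1e-12)
  # open-shell singles are nonzero
  expect_gt(abs(res[[1]]$singles), 1e-8)
})

test_that("PCD-restricted auxiliaries reproduce the full-set ED MP2 closely", {
  ref <- ref_ch3_sto()
  cfg_full <- lnocc_config("none")
  cfg_pcd <- lnocc_config("none", T_0 = 0.985)   # compact PCD, everything else exact
  st <- pair_setup(ref, "ch3_sto", cfg_full)
  e_full <- ed_mp2_energy(assemble_ed(1, ref, st$lmos, st$paos, st$pairlist,
                                      cfg_full, fods = st$fods))$energy
  e_pcd <- ed_mp2_energy(assemble_ed(1, ref, st$lmos, st$paos, st$pairlist,
                                     cfg_pcd, fods = st$fods))$energy
  expect_lt(abs(e_full - e_pcd), 1e-5)
})
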