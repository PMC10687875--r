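# LNO construction: density fragments, SOMO-block zeroing, the
# factor-2 scaling for SO central LMOs, threshold truncation and the
# LIS limits.

lno_inputs <- function(ref, key, L, preset = "none") {
  cfg <- lnocc_config(preset)
  st <- pair_setup(ref, key, cfg)
  memo(paste0("lno_", key, "_", preset, "_", L), {
    ed <- assemble_ed(L, ref, st$lmos, st$paos, st$pairlist, cfg, fods = st$fods)
    mp2 <- ed_mp2_energy(ed, keep_amplitudes = TRUE)
    list(ed = ed, mp2 = mp2)
  })
}

test_that("occupied fragment: PSD, zeroed blocks, SO scaling", {
  ref <- ref_ch3_sto()
  somo <- which(pair_setup(ref, "ch3_sto", lnocc_config("none"))$lmos$origin == "SOMO")
  for (L in c(1L, somo)) {
    inp <- lno_inputs(ref, "ch3_sto", L)
    of <- occupied_density_fragment(inp$ed, inp$mp2$amps)
    ev <- eigen(of$D, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
    expect_true(all(abs(of$D[1, ]) == 0))
    expect_equal(of$scale, if (inp$ed$is_somo[1]) 2 else 1)
    expect_gt(sum(diag(of$D_raw)), 0)
    if (length(inp$ed$somo_cols) > 0) {
      oth <- setdiff(seq_len(ncol(inp$ed$occ_rest)), inp$ed$somo_cols)
      expect_true(all(of$D[inp$ed$somo_cols, oth] == 0))
    }
  }
  # SO central: the spin-down amplitude blocks vanish identically
  inp <- lno_inputs(ref, "ch3_sto", somo)
  expect_null(inp$mp2$amps$dd)
  expect_null(inp$mp2$amps$du)
})

test_that("zero amplitudes give zero fragments", {
  inp <- lno_inputs(ref_ch3_sto(), "ch3_sto", 1L)
  z <- inp$mp2$amps
  z$uu <- z$uu * 0; z$ud <- z$ud * 0; z$dd <- z$dd * 0; z$du <- z$du * 0
  of <- occupied_density_fragment(inp$ed, z)
  expect_equal(max(abs(of$D)), 0)
  ko <- select_occupied_lnos(inp$ed, of, 1e-5)
  vf <- virtual_density_fragment(inp$ed, z, ko)
  expect_equal(max(abs(vf$D)), 0)
})

test_that("no truncation reproduces the full ED spaces and energies", {
  ref <- ref_ch3_sto()
  for (L in c(1L, 4L)) {
    inp <- lno_inputs(ref, "ch3_sto", L)
    lis <- build_lis(inp$ed, inp$mp2, 0, 0)
    expect_equal(ncol(lis$occ_rest), ncol(inp$ed$occ_rest))
    expect_equal(ncol(lis$vir_rest), ncol(inp$ed$vir_rest))
    lmp2 <- ed_mp2_energy(lis)
    expect_equal(lmp2$energy, inp$mp2$energy, tolerance = 1e-10)
  }
})

test_that("occupation spectra are descending and kept counts monotone in the threshold", {
  ref <- memo("ref_ethyl_dz", build_reference(generate_fixture("ethyl"), "6-31g"))
  inp <- lno_inputs(ref, "ethyl_dz", 1L)
  lis1 <- build_lis(inp$ed, inp$mp2, 1e-4, 1e-5)
  lis2 <- build_lis(inp$ed, inp$mp2, 1e-5, 1e-6)
  lis3 <- build_lis(inp$ed, inp$mp2, 1e-6, 1e-7)
  expect_true(all(diff(lis1$vir_spectrum) <= 1e-12))
  expect_lte(ncol(lis1$occ_rest), ncol(lis2$occ_rest))
  expect_lte(ncol(lis2$occ_rest), ncol(lis3$occ_rest))
  expect_lte(ncol(lis1$vir_rest), ncol(lis2$vir_rest))
  # the virtual LNO truncation genuinely compresses the space (at the
  # double-zeta level of this fixture the cut bites at looser thresholds)
  expect_lt(ncol(lis1$vir_rest), ncol(inp$ed$vir_rest))
  lisn <- build_lis(inp$ed, inp$mp2, 1e-5, 1e-6)
  expect_lte(ncol(lisn$vir_rest), ncol(inp$ed$vir_rest))
  # central LMO is kept exactly
  ov <- crossprod(lisn$occ_rest[, 1], inp$ed$Sed %*% inp$ed$occ_rest[, 1])
  expect_gt(abs(ov), 1 - 1e-10)
})

test_that("virtual fragment shrinks weakly when fewer occupied LNOs are kept", {
  ref <- memo("ref_ethyl_dz", build_reference(generate_fixture("ethyl"), "6-31g"))
  inp <- lno_inputs(ref, "ethyl_dz", 1L)
  of <- occupied_density_fragment(inp$ed, inp$mp2$amps)
  ko_all <- select_occupied_lnos(inp$ed, of, 0)
  ko_few <- select_occupied_lnos(inp$ed, of, 1e-3)
  vf_all <- virtual_density_fragment(inp$ed, inp$mp2$amps, ko_all)
  vf_few <- virtual_density_fragment(inp$ed, inp$mp2$amps, ko_few)
  expect_lte(sum(diag(vf_few$D)), sum(diag(vf_all$D)) + 1e-12)
})

test_that("closed-shell spin-up and spin-down virtual contributions are equal", {
  ref <- ref_water_sto()
  inp <- lno_inputs(ref, "water_sto", 1L)
  a <- inp$mp2$amps
  expect_equal(a$uu, a$dd, tolerance = 1e-10)
  expect_equal(a$ud, aperm(a$du, c(1, 2, 3)), tolerance = 1e-10)
})
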