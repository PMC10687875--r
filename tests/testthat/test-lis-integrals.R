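# PAO'/LNO' two-external route, SOMO dual-role completion, and NAF
# compression.

lis_setup <- function(ref, key, L = 1L, preset = "none") {
  cfg <- lnocc_config(preset)
  st <- pair_setup(ref, key, cfg)
  memo(paste0("lisint_", key, "_", preset, "_", L), {
    ed <- assemble_ed(L, ref, st$lmos, st$paos, st$pairlist, cfg, fods = st$fods)
    mp2 <- ed_mp2_energy(ed, keep_amplitudes = TRUE)
    lis <- build_lis(ed, mp2, cfg$eps_o, cfg$eps_v)
    list(ed = ed, lis = lis)
  })
}

test_that("PAO' functions are orthogonal to the ED occupied space", {
  s <- lis_setup(ref_ch3_sto(), "ch3_sto")
  Q <- build_pao_prime(s$ed)$Q
  dev <- crossprod(Q, s$ed$Sed %*% s$ed$occ_rest)
  expect_lt(max(abs(dev)), 1e-8)
  # PCD covering all ED atoms: PAO' spans the full ED virtual space
  tx <- two_external_integrals(s$lis, s$ed)
  expect_lt(max(tx$deficit), 1e-8)
})

test_that("assembled two-external ERIs are symmetric and dual-role blocks consistent", {
  s <- lis_setup(ref_ch3_sto(), "ch3_sto")
  li <- lis_integrals(s$lis, s$ed, eps_naf = 0)
  for (sp in c("up", "dn")) {
    Bvv <- li[[sp]]$Bvv
    nv <- dim(Bvv)[1]
    eri <- tcrossprod(matrix(Bvv, nv * nv, dim(Bvv)[3]))
    eri <- array(eri, c(nv, nv, nv, nv))
    expect_equal(eri, aperm(eri, c(3, 4, 1, 2)), tolerance = 1e-10)
  }
  # closed-shell limit: spin blocks identical
  sw <- lis_setup(ref_water_sto(), "water_sto")
  lw <- lis_integrals(sw$lis, sw$ed, eps_naf = 0)
  expect_equal(lw$up$Bvv, lw$dn$Bvv, tolerance = 1e-12)
  expect_equal(lw$up$Bov, lw$dn$Bov, tolerance = 1e-12)
})

test_that("NAF counts shrink with the threshold and eps_naf = 0 is exact", {
  s <- lis_setup(ref_ch3_sto(), "ch3_sto")
  li0 <- lis_integrals(s$lis, s$ed, eps_naf = 0)
  li1 <- lis_integrals(s$lis, s$ed, eps_naf = 1e-2)
  li2 <- lis_integrals(s$lis, s$ed, eps_naf = 1e-1)
  expect_equal(li0$n_naf, s$ed$naux)
  expect_gte(li1$n_naf, li2$n_naf)
  expect_lt(li1$n_naf, li0$n_naf)
  # a single shared NAF basis serves both spins: mixed-spin ERIs are
  # assembled from tensors with one common auxiliary dimension
  expect_equal(dim(li1$up$Bov)[3], dim(li1$dn$Bov)[3])
})

test_that("LIS CCSD with the LNO' integrals matches the domain MP2 machinery", {
  # structural check: the spin-orbital system built from the LIS
  # integral lists reproduces the LIS MP2 energy of the Laplace route
  s <- lis_setup(ref_ch3_sto(), "ch3_sto")
  li <- lis_integrals(s$lis, s$ed, eps_naf = 0)
  sys <- so_system(li)
  D2 <- outer(outer(sys$eps_occ, sys$eps_occ, "+"),
              outer(sys$eps_vir, sys$eps_vir, "+"), "-")
  V <- soV(sys, "oovv")
  emp2_doubles <- 0.25 * sum(V^2 / D2)
  lmp2 <- ed_mp2_energy(s$lis)
  tot_doubles <- memo("lis_mp2_doubles_sum_ch3", {
    st <- pair_setup(ref_ch3_sto(), "ch3_sto", lnocc_config("none"))
    sum(vapply(seq_len(ncol(st$lmos$C)), function(L) {
      sl <- lis_setup(ref_ch3_sto(), "ch3_sto", L)
      ed_mp2_energy(sl$lis)$doubles
    }, 0))
  })
  expect_equal(tot_doubles, emp2_doubles, tolerance = 1e-6)
  expect_lt(lmp2$energy, 0)
})
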