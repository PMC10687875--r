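# Spin-orbital coupled cluster: FCI anchors, solver cross-validation,
# the per-orbital energy partition, and both triples codes.

test_that("CCSD equals FCI for two-electron systems (both solvers)", {
  for (key in c("h2_sto", "h2_dz")) {
    ref <- if (key == "h2_sto") ref_h2_sto() else ref_h2_dz()
    sys <- memo(paste0("sys_", key), oracle_so_system(ref))
    fci <- memo(paste0("fci_", key), fci_two_electron(sys))
    ccA <- memo(paste0("ccA_", key), ccsd_solve(sys, conv = 1e-10))
    ccB <- memo(paste0("ccB_", key), oracle_ccsd(sys, conv = 1e-10))
    expect_equal(ccA$energy, fci$E_corr, tolerance = 1e-9)
    expect_equal(ccB$energy, fci$E_corr, tolerance = 1e-9)
  }
})

test_that("H2 has no triples correction", {
  sys <- memo("sys_h2_dz", oracle_so_system(ref_h2_dz()))
  cc <- memo("ccA_h2_dz", ccsd_solve(sys, conv = 1e-10))
  expect_equal(oracle_triples(sys, cc), 0)
})

test_that("the two CCSD transcriptions agree on an open-shell radical", {
  ref <- ref_ch3_sto()
  sys <- memo("sys_ch3_sto", oracle_so_system(ref))
  ccA <- memo("ccA_ch3_sto", ccsd_solve(sys, conv = 1e-9))
  ccB <- memo("ccB_ch3_sto", oracle_ccsd(sys, conv = 1e-9))
  expect_equal(ccA$energy, ccB$energy, tolerance = 1e-9)
})

test_that("first-order spin-orbital energy equals the independent MP2 oracle", {
  ref <- ref_ch3_sto()
  sys <- memo("sys_ch3_sto", oracle_so_system(ref))
  D2 <- outer(outer(sys$eps_occ, sys$eps_occ, "+"),
              outer(sys$eps_vir, sys$eps_vir, "+"), "-")
  V <- soV(sys, "oovv")
  emp2 <- 0.25 * sum(V^2 / D2) +
    sum(sys$f_ov^2 / outer(sys$eps_occ, sys$eps_vir, "-"))
  om <- memo("omp2_ch3", oracle_mp2(ref))
  expect_equal(emp2, om$E_corr, tolerance = 1e-10)
})

test_that("the per-orbital CCSD partition sums to the total energy", {
  sys <- memo("sys_ch3_sto", oracle_so_system(ref_ch3_sto()))
  cc <- memo("ccA_ch3_sto", ccsd_solve(sys, conv = 1e-9))
  M <- ccsd_energy_matrix(sys, cc)
  expect_equal(sum(diag(M)), cc$energy, tolerance = 1e-10)
  # trace is invariant under any occupied rotation of the projectors
  set.seed(11)
  Q <- qr.Q(qr(matrix(rnorm(sys$no^2), sys$no)))
  expect_equal(sum(diag(crossprod(Q, M %*% Q))), cc$energy, tolerance = 1e-10)
})

test_that("Laplace central-restricted (T) matches the explicit-denominator oracle", {
  sys <- memo("sys_ch3_sto", oracle_so_system(ref_ch3_sto()))
  cc <- memo("ccA_ch3_sto", ccsd_solve(sys, conv = 1e-9))
  et <- memo("et_ch3_sto", oracle_triples(sys, cc))
  expect_lt(et, 0)
  rng <- triples_range(sys)
  mu <- (max(sys$eps_occ) + min(sys$eps_vir)) / 2
  lap_sum <- function(tol) {
    quad <- laplace_quadrature_cached(rng$x_min, rng$x_max, tol)
    tot <- 0
    for (i in seq_len(sys$no)) {
      u <- rep(0, sys$no); u[i] <- 1
      tot <- tot + cpp_triples_central(sys$eps_occ, sys$eps_vir, sys$f_ov,
                                       cc$t1, cc$t2, soV(sys, "oovv"),
                                       soV(sys, "vovv"), soV(sys, "ovoo"),
                                       u, quad$t, quad$w, mu)
    }
    tot
  }
  d2 <- abs(lap_sum(1e-2) - et)
  d4 <- abs(lap_sum(1e-4) - et)
  expect_lt(d2, max(1e-6, 1e-2 * abs(et)))
  expect_lt(d4, d2)
})

test_that("zero doubles amplitudes give zero triples", {
  sys <- memo("sys_ch3_sto", oracle_so_system(ref_ch3_sto()))
  cc <- memo("ccA_ch3_sto", ccsd_solve(sys, conv = 1e-9))
  z <- list(t1 = cc$t1 * 0, t2 = cc$t2 * 0)
  expect_equal(oracle_triples(sys, z), 0)
})
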