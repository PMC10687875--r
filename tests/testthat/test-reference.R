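# SCF reference determinants: RHF/ROHF/UHF-QRO paths, DOMO/SOMO
# partition, frozen core, and the off-diagonal Fock contract.

test_that("H2/STO-3G reference energy matches the textbook value", {
  ref <- ref_h2_sto()
  expect_equal(ref$scf_energy, -1.1167, tolerance = 1e-3)
  expect_length(ref$somo_idx, 0)
  expect_equal(ref$fock_up, ref$fock_down)
})

test_that("closed-shell reference has identical spin Fock matrices and no SOMOs", {
  ref <- ref_water_sto()
  expect_identical(ref$fock_up, ref$fock_down)
  expect_length(ref$somo_idx, 0)
  expect_equal(ref$frozen_core_idx, 1L)        # oxygen 1s
  # orbital orthonormality in the overlap metric
  dev <- crossprod(ref$C, ref$ints$S %*% ref$C) - diag(ref$ints$nbf)
  expect_lt(max(abs(dev)), 1e-10)
})

test_that("doublet radical carries exactly one SOMO", {
  ref <- ref_ch3_sto()
  expect_length(ref$somo_idx, 1)
  expect_equal(length(ref$somo_idx), ref$mol$multiplicity - 1L)
})

test_that("QRO and ROHF references agree to chemical tolerance", {
  ref <- ref_ch3_sto()
  qro <- memo("qro_ch3", build_reference(generate_fixture("methyl"), "sto-3g",
                                         mode = "uhf_qro"))
  expect_lt(abs(qro$scf_energy - ref$scf_energy), 1e-4)
  expect_length(qro$somo_idx, 1)
})

test_that("impossible charge/multiplicity combinations are rejected", {
  expect_error(molecule("O", matrix(0, 1, 3), 0L, 2L), "incompatible")
  expect_error(molecule(c("H", "H"), matrix(0, 2, 3), 0L, 4L), "incompatible")
})

test_that("off-diagonal Fock vanishes for self-consistent references only", {
  fod_w <- build_fock_offdiagonal(ref_water_sto())
  expect_lt(max(abs(fod_w$up)), 1e-8)
  fod_c <- memo("fod_ch3", build_fock_offdiagonal(ref_ch3_sto()))
  expect_gt(max(abs(fod_c$up)), 1e-4)
  expect_equal(fod_c$up, t(fod_c$up), tolerance = 1e-10)
  expect_equal(fod_c$down, t(fod_c$down), tolerance = 1e-10)
})

test_that("semicanonicalization diagonalizes the Fock block", {
  ref <- ref_ch3_sto()
  occ <- ref$C[, seq_len(ref$na)]
  sc <- semicanonicalize(occ, ref$fock_up, ref$ints$S)
  Fb <- crossprod(sc$C, ref$fock_up %*% sc$C)
  expect_lt(max(abs(Fb - diag(sc$eps))), 1e-10)
  # occupied-virtual block is generally nonzero for an ROHF reference
  vir <- ref$C[, ref$virt_idx]
  scv <- semicanonicalize(vir, ref$fock_up)
  fov <- crossprod(sc$C, ref$fock_up %*% scv$C)
  expect_gt(max(abs(fov)), 1e-6)
  expect_error(semicanonicalize(2 * occ, ref$fock_up, ref$ints$S),
               "not orthonormal")
})

test_that("XYZ round trip preserves the geometry", {
  m <- generate_fixture("ethyl")
  p <- tempfile(fileext = ".xyz")
  write_xyz(m, p)
  m2 <- read_xyz(p, charge = 0L, multiplicity = 2L)
  expect_equal(m2$coords, m$coords, tolerance = 1e-7)
  expect_identical(m2$atoms, m$atoms)
  expect_error(read_xyz(tempfile()), "not found")
})

test_that("fixture generators honor their constructive invariants", {
  for (n in c(1, 3, 5))
    expect_length(generate_fixture("radical_chain", n)$atoms, 3 * n + 1)
  cc <- generate_fixture("closed_chain", 3)
  expect_equal(cc$multiplicity, 1L)
  expect_length(cc$atoms, 3 * 3 + 2)
  expect_equal(generate_fixture("radical_chain", 1)$multiplicity, 2L)
  expect_error(generate_fixture("nonsense"), "unknown fixture")
  # determinism
  expect_identical(generate_fixture("radical_chain", 4)$coords,
                   generate_fixture("radical_chain", 4)$coords)
})
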