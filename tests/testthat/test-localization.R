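# Restricted Boys localization: objective increase, unitary
# invariance, subspace separation.

test_that("localization strictly increases the Boys objective", {
  ref <- ref_ethyl_sto()
  lm <- lmos_of(ref, "ethyl_sto")
  expect_gt(lm$objective_after, lm$objective_before)
})

test_that("localized orbitals span the same density and stay orthonormal", {
  ref <- ref_water_sto()
  lm <- lmos_of(ref, "water_sto")
  corr <- setdiff(ref$domo_idx, ref$frozen_core_idx)
  P1 <- tcrossprod(ref$C[, corr])
  P2 <- tcrossprod(lm$C[, lm$origin == "DOMO"])
  expect_lt(max(abs(P1 - P2)), 1e-8)
  dev <- crossprod(lm$C, ref$ints$S %*% lm$C) - diag(ncol(lm$C))
  expect_lt(max(abs(dev)), 1e-10)
})

test_that("DOMO and SOMO subspaces are never mixed", {
  ref <- ref_ch3_sto()
  lm <- lmos_of(ref, "ch3_sto")
  Ps <- tcrossprod(ref$C[, ref$somo_idx])
  Pl <- tcrossprod(lm$C[, lm$origin == "SOMO"])
  expect_lt(max(abs(Ps - Pl)), 1e-8)
  expect_equal(lm$occupation, c(rep(2L, sum(lm$origin == "DOMO")),
                                rep(1L, sum(lm$origin == "SOMO"))))
})

test_that("a single orbital is returned unchanged up to sign", {
  ref <- ref_ch3_sto()
  lm <- lmos_of(ref, "ch3_sto")
  s0 <- fix_sign(ref$C[, ref$somo_idx, drop = FALSE])
  s1 <- lm$C[, lm$origin == "SOMO", drop = FALSE]
  expect_equal(abs(s0), abs(s1), tolerance = 1e-10)
})

test_that("localization is deterministic", {
  ref <- ref_water_sto()
  a <- localize_boys_restricted(ref)
  b <- localize_boys_restricted(ref)
  expect_identical(a$C, b$C)
})
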