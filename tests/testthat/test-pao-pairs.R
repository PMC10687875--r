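# PAOs, Boughton-Pulay lists, primary domains, pair energies and the
# strong/distant classification.

test_that("PAOs are orthogonal to all occupied orbitals and span the virtual space", {
  ref <- ref_ch3_sto()
  lm <- lmos_of(ref, "ch3_sto")
  pa <- paos_of(ref, lm, "ch3_sto")
  S <- ref$ints$S
  expect_lt(max(abs(crossprod(pa$C, S %*% lm$C))), 1e-8)
  expect_lt(max(abs(crossprod(pa$C, S %*% ref$C[, ref$frozen_core_idx]))), 1e-8)
  ev <- eigen(crossprod(pa$C, S %*% pa$C), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-7), ref$ints$nbf - ref$na)
  expect_equal(ncol(pa$C), ref$ints$nbf)   # one PAO per AO before dropping
})

test_that("BP atom lists behave monotonically and are tight", {
  ref <- ref_water_sto()
  lm <- lmos_of(ref, "water_sto")
  v <- lm$C[, 1]
  expect_error(bp_atom_list(v, 1.5, ref), "in \\(0,1\\]")
  b1 <- bp_atom_list(v, 0.90, ref)
  b2 <- bp_atom_list(v, 0.98, ref)
  expect_gte(b2$completeness, b1$completeness)
  expect_gte(b1$completeness, 0.90)
  # T -> 1 includes every atom
  ball <- bp_atom_list(v, 1.0, ref)
  expect_setequal(ball$atoms, seq_along(ref$mol$atoms))
  # removing the last atom drops completeness below T
  if (length(b2$atoms) > 1)
    expect_lt(b2$trace[length(b2$trace) - 1], 0.98)
})

test_that("water-dimer lone-pair BP lists stay on one monomer", {
  ref <- memo("ref_wd", build_reference(generate_fixture("water_dimer"), "sto-3g"))
  lm <- lmos_of(ref, "wd")
  mono1 <- 1:3; mono2 <- 4:6
  for (i in seq_len(ncol(lm$C))) {
    bp <- bp_atom_list(lm$C[, i], 0.98, ref)
    expect_true(all(bp$atoms %in% mono1) || all(bp$atoms %in% mono2))
  }
})

test_that("primary domains contain their LMO's BP atoms and admit SOMOs", {
  ref <- ref_ch3_sto()
  st <- pair_setup(ref, "ch3_sto")
  for (i in seq_along(st$pds)) {
    pd <- st$pds[[i]]
    expect_true(all(pd$bp_atoms %in% pd$atoms))
  }
  # small radical: every PD covers the whole molecule, and DOMO-centered
  # PDs admit the SOMO to the spin-down virtual space
  somo_col <- which(st$lmos$origin == "SOMO")
  expect_setequal(st$pds[[1]]$atoms, seq_along(ref$mol$atoms))
  expect_true(somo_col %in% st$pds[[1]]$somo_in)
  # closed-shell molecule: no SOMO admission ever triggers
  refw <- ref_water_sto()
  stw <- pair_setup(refw, "water_sto")
  expect_true(all(vapply(stw$pds, function(p) length(p$somo_in) == 0, TRUE)))
})

test_that("pair energies are negative, symmetric, and decay with separation", {
  ref <- ref_ch3_sto()
  st <- pair_setup(ref, "ch3_sto")
  e12 <- multipole_pair_energy(1, 2, st$pds, ref, st$lmos)
  expect_lt(e12, 0)
  expect_identical(e12, multipole_pair_energy(2, 1, st$pds, ref, st$lmos))
})

test_that("classification follows the threshold rules and the M window", {
  ref <- ref_ch3_sto()
  st <- pair_setup(ref, "ch3_sto")
  pl <- st$pairlist
  fw <- pl$f_w
  eps_w <- pl$eps_w
  for (r in seq_len(nrow(pl$pairs))) {
    row <- pl$pairs[r, ]
    if (abs(row$epair) >= row$f_w * eps_w) {
      expect_identical(row$classification, "strong")
      expect_true(is.na(row$M))         # no M evaluation above threshold
    }
  }
  # closed-shell system: every pair is DO-DO with f_w = 1
  stw <- pair_setup(ref_water_sto(), "water_sto")
  expect_true(all(stw$pairlist$pairs$spin_class == "dd"))
  expect_true(all(stw$pairlist$pairs$f_w == 1))
  # pair CSV export
  p <- tempfile(fileext = ".csv")
  write_pair_table(pl, p)
  expect_true(file.exists(p))
  expect_equal(nrow(utils::read.csv(p)), nrow(pl$pairs))
})

test_that("strong-pair sets grow monotonically as eps_w is tightened", {
  ref <- ref_ethyl_sto()
  st <- pair_setup(ref, "ethyl_sto")
  lab <- function(pl) with(pl$pairs[pl$pairs$classification == "strong", ],
                           paste(k, l))
  pls <- lapply(c(1e-3, 1e-4, 1e-5), function(ew)
    classify_pairs(ref, st$lmos, st$paos, st$pds, eps_w = ew))
  expect_true(all(lab(pls[[1]]) %in% lab(pls[[2]])))
  expect_true(all(lab(pls[[2]]) %in% lab(pls[[3]])))
})

test_that("Mulliken promotion measure vanishes for disjoint LMOs", {
  ref <- memo("ref_wd", build_reference(generate_fixture("water_dimer"), "sto-3g"))
  st <- pair_setup(ref, "wd")
  pl <- st$pairlist$pairs
  # inter-monomer pairs evaluated in the borderline window must have tiny M
  inter <- !is.na(pl$M)
  if (any(inter)) expect_true(all(abs(pl$M[inter]) < 0.5))
})
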