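# Configuration presets, domain routing, bookkeeping identities, and
# report/CLI plumbing.

test_that("configuration presets resolve to the published defaults", {
  cfg <- lnocc_config("normal")
  expect_equal(cfg$eps_o, 1e-5)
  expect_equal(cfg$eps_v, 1e-6)
  expect_equal(cfg$eps_w, 1e-5)
  expect_equal(cfg$T_EDo, 0.9999)
  expect_equal(cfg$eps_naf, 1e-2)
  expect_equal(cfg$T_LT, 1e-2)
  expect_equal(cfg$g_w, 5)
  expect_equal(cfg$h_w, 50)
  tight <- lnocc_config("tight")
  expect_equal(tight$eps_o, 1e-6)
  expect_equal(tight$eps_v, 1e-7)
  expect_equal(tight$eps_w, 1e-6)
  expect_error(lnocc_config("normal", nonsense = 1), "unknown configuration")
})

test_that("YAML configuration uses the flat keyword namespace", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("preset: normal", "lnoepso: 1.0e-6", "wpairtol: 1.0e-4",
               "laptol: 1.0e-3", "epairscale: 7", "f_w_ss: 0.3"), p)
  cfg <- read_config_yaml(p)
  expect_equal(cfg$eps_o, 1e-6)
  expect_equal(cfg$eps_w, 1e-4)
  expect_equal(cfg$T_LT, 1e-3)
  expect_equal(cfg$g_w, 7)
  expect_equal(cfg$f_w[["ss"]], 0.3)
  expect_equal(cfg$eps_v, 1e-6)    # untouched default
})

test_that("domain routing follows the SOMO-in-ED rule", {
  ref <- ref_ch3_sto()
  st <- pair_setup(ref, "ch3_sto")
  cfg_on <- lnocc_config("normal", spin_polarization_approx = TRUE)
  cfg_off <- lnocc_config("normal", spin_polarization_approx = FALSE)
  # CH3: every ED contains the SOMO -> never spin-averaged
  for (L in seq_len(ncol(st$lmos$C)))
    expect_identical(route_domain(L, st$lmos, st$pairlist, cfg_on), "unrestricted")
  # closed shell with the approximation on: always spin-averaged
  refw <- ref_water_sto()
  stw <- pair_setup(refw, "water_sto")
  for (L in seq_len(ncol(stw$lmos$C))) {
    expect_identical(route_domain(L, stw$lmos, stw$pairlist, cfg_on), "spin_averaged")
    expect_identical(route_domain(L, stw$lmos, stw$pairlist, cfg_off), "unrestricted")
  }
})

test_that("energy report identities hold to machine bookkeeping precision", {
  rep <- memo("rep_water_normal",
              lnocc_energy(generate_fixture("water"), "sto-3g", lnocc_config()))
  tab <- rep$per_lmo
  expect_equal(rep$E_corr,
               sum(tab$dE_ccsd) + sum(tab$dE_t) + sum(tab$dE_mp2_ed) -
                 sum(tab$dE_mp2_lis) + rep$distant_pair_energy,
               tolerance = 1e-12)
  expect_equal(rep$E_lmp2, sum(tab$dE_mp2_ed) + rep$distant_pair_energy,
               tolerance = 1e-12)
  expect_equal(rep$E_total, rep$E_scf + rep$E_corr, tolerance = 1e-12)
})

test_that("reports are deterministic across repeated runs", {
  r1 <- memo("rep_water_normal",
             lnocc_energy(generate_fixture("water"), "sto-3g", lnocc_config()))
  r2 <- lnocc_energy(generate_fixture("water"), "sto-3g", lnocc_config())
  expect_identical(r1$E_corr, r2$E_corr)
  expect_identical(r1$per_lmo$dE_ccsd, r2$per_lmo$dE_ccsd)
})

test_that("JSON and CSV report writers round-trip the totals", {
  rep <- memo("rep_water_normal",
              lnocc_energy(generate_fixture("water"), "sto-3g", lnocc_config()))
  pj <- tempfile(fileext = ".json"); pc <- tempfile(fileext = ".csv")
  write_report_json(rep, pj)
  write_report_csv(rep, pc)
  j <- jsonlite::read_json(pj)
  expect_equal(j$E_corr, rep$E_corr, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(pc)), nrow(rep$per_lmo))
})

test_that("the command-line entry point runs and reports errors", {
  cli <- file.path(find.package("lnocc"), "exec", "lnocc")
  expect_true(file.exists(cli))
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(h2_molecule(), xyz)
  out <- tempfile(fileext = ".json")
  st <- system2("Rscript", c(cli, xyz, "--basis", "sto-3g", "--preset", "normal",
                             "--out", out), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(st, "status"), NULL)     # exit code 0
  expect_true(file.exists(out))
  j <- jsonlite::read_json(out)
  expect_lt(j$E_corr, 0)
  st2 <- suppressWarnings(
    system2("Rscript", c(cli, tempfile(fileext = ".xyz")),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st2, "status")))  # nonzero exit
})
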