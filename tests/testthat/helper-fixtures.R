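# Session-level memoization of the expensive shared objects (references,
# localizations, oracle energies).  Everything is built from code at
# test time; no stored fixtures.

# internal helpers exercised directly by the unit tests
ANGSTROM_TO_BOHR <- lnocc:::ANGSTROM_TO_BOHR
cpp_overlap <- lnocc:::cpp_overlap
cpp_kinetic <- lnocc:::cpp_kinetic
cpp_nuclear <- lnocc:::cpp_nuclear
cpp_eri2c <- lnocc:::cpp_eri2c
cpp_eri3c <- lnocc:::cpp_eri3c
cpp_triples_central <- lnocc:::cpp_triples_central
ec <- lnocc:::ec
soV <- lnocc:::soV
domain_spin_bases <- lnocc:::domain_spin_bases
domain_quadrature <- lnocc:::domain_quadrature
laplace_eval <- lnocc:::laplace_eval
laplace_quadrature_cached <- lnocc:::laplace_quadrature_cached
lmo_centroids <- lnocc:::lmo_centroids
fix_sign <- lnocc:::fix_sign
triples_range <- lnocc:::triples_range

.lnocc_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.lnocc_test_cache[[key]]))
    assign(key, force(expr), envir = .lnocc_test_cache)
  .lnocc_test_cache[[key]]
}

h2_molecule <- function() {
  molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4 / ANGSTROM_TO_BOHR)),
           0L, 1L, "H2")
}

ref_h2_sto <- function() memo("ref_h2_sto", build_reference(h2_molecule(), "sto-3g"))
ref_h2_dz <- function() memo("ref_h2_dz", build_reference(h2_molecule(), "6-31g"))
ref_water_sto <- function() memo("ref_water_sto",
                                 build_reference(generate_fixture("water"), "sto-3g"))
ref_ch3_sto <- function() memo("ref_ch3_sto",
                               build_reference(generate_fixture("methyl"), "sto-3g"))
ref_ch3_dz <- function() memo("ref_ch3_dz",
                              build_reference(generate_fixture("methyl"), "6-31g"))
ref_ethyl_sto <- function() memo("ref_ethyl_sto",
                                 build_reference(generate_fixture("ethyl"), "sto-3g"))

lmos_of <- function(ref, key) memo(paste0("lmos_", key), localize_boys_restricted(ref))
paos_of <- function(ref, lmos, key) memo(paste0("paos_", key), build_paos(ref, lmos))

# full PD/pair machinery for a reference, memoized
pair_setup <- function(ref, key, config = lnocc_config()) {
  memo(paste0("pairs_", key, "_", config$preset), {
    lmos <- localize_boys_restricted(ref)
    paos <- build_paos(ref, lmos)
    pds <- lapply(seq_len(ncol(lmos$C)), build_primary_domain,
                  ref = ref, lmos = lmos, paos = paos,
                  T_PDo = config$T_PDo, T_PDv = config$T_PDv)
    pairlist <- classify_pairs(ref, lmos, paos, pds,
                               eps_w = config$eps_w, g_w = config$g_w,
                               h_w = config$h_w, f_w = config$f_w,
                               mode = config$pair_energy_mode,
                               T_PDo = config$T_PDo)
    list(lmos = lmos, paos = paos, pds = pds, pairlist = pairlist,
         fods = build_fock_offdiagonal(ref))
  })
}

oracle_of <- function(ref, key) memo(paste0("oracle_", key), canonical_ccsdt_oracle(ref))
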