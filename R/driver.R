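# Pipeline driver: routes each central LMO's domain through the
# unrestricted or spin-averaged path, runs ED MP2 -> LNO -> LIS
# CCSD(T), and assembles the total LNO-CCSD(T) correlation energy with
# the MP2-level truncation corrections and distant-pair energies.

#' Route a domain: unrestricted or spin-averaged
#'
#' The spin-averaged (closed-shell-like) path applies when the
#' long-range spin-polarization approximation is enabled and the
#' extended domain contains no SOMO: all ED Fock blocks are replaced by
#' their spin average, so both spin channels are identical.
#'
#' @param central central LMO index.
#' @param lmos LMO set.
#' @param pairlist classified pairs.
#' @param config configuration.
#' @return \code{"spin_averaged"} or \code{"unrestricted"}.
#' @export
route_domain <- function(central, lmos, pairlist, config) {
  if (!config$spin_polarization_approx) return("unrestricted")
  prs <- pairlist$pairs
  strong <- prs[prs$classification == "strong", , drop = FALSE]
  partners <- unique(c(strong$l[strong$k == central],
                       strong$k[strong$l == central]))
  ids <- c(central, partners)
  if (any(lmos$origin[ids] == "SOMO")) "unrestricted" else "spin_averaged"
}

# run one domain end to end; returns the per-LMO record
.run_domain <- function(central, ref, lmos, paos, pairlist, config, fods,
                        verbose = FALSE) {
  path <- route_domain(central, lmos, pairlist, config)
  ed <- assemble_ed(central, ref, lmos, paos, pairlist, config,
                    spin_free = (path == "spin_averaged"), fods = fods)
  edmp2 <- ed_mp2_energy(ed, keep_amplitudes = TRUE)
  lis <- build_lis(ed, edmp2, config$eps_o, config$eps_v)
  lismp2 <- ed_mp2_energy(lis)
  li <- lis_integrals(lis, ed, config$eps_naf)
  sys <- so_system(li)
  cc <- ccsd_solve(sys, conv = config$cc_conv, maxiter = config$cc_maxiter)
  de_ccsd <- ccsd_contribution(sys, cc)
  rng <- triples_range(sys)
  quad_t <- laplace_quadrature_cached(rng$x_min, rng$x_max, config$T_LT)
  de_t <- triples_contribution_laplace(sys, cc, quad_t)
  if (verbose)
    message(sprintf(
      "  LMO %3d [%s/%s] ED %d AOs -> LIS %dx%d  dE(CCSD) %.8f  dE(T) %.8f  it %d",
      central, lmos$origin[central],
      if (path == "spin_averaged") "avg" else "unr",
      length(ed$ao), ncol(lis$occ_rest), ncol(lis$vir_rest),
      de_ccsd, de_t, cc$niter))
  list(lmo = central, origin = lmos$origin[central], path = path,
       dE_ccsd = de_ccsd, dE_t = de_t,
       dE_mp2_ed = edmp2$energy, dE_mp2_lis = lismp2$energy,
       n_atoms_ed = length(ed$atoms), n_ao_ed = length(ed$ao),
       n_occ_ed = ncol(ed$occ_rest), n_pao_ed = ncol(ed$vir_rest),
       n_occ_lis = ncol(lis$occ_rest), n_vir_lis = ncol(lis$vir_rest),
       n_naf = li$n_naf, cc_niter = cc$niter)
}

#' Assemble the energy report from per-domain results
#'
#' @param domains list of per-domain records.
#' @param pairlist classified pair list (supplies distant-pair energies).
#' @param ref reference state.
#' @return \code{lnocc_report} with per-LMO table and totals; refuses a
#'   total when any domain failed.
#' @export
assemble_energy <- function(domains, pairlist, ref) {
  failed <- vapply(domains, function(d) inherits(d, "error") || is.null(d$dE_ccsd), TRUE)
  if (any(failed))
    stop("domain(s) failed: ", paste(which(failed), collapse = ", "),
         "; no total energy is emitted")
  ord <- order(vapply(domains, `[[`, 0, "lmo"))
  domains <- domains[ord]
  tab <- do.call(rbind, lapply(domains, function(d)
    data.frame(lmo = d$lmo, origin = d$origin, path = d$path,
               dE_ccsd = d$dE_ccsd, dE_t = d$dE_t,
               dE_mp2_ed = d$dE_mp2_ed, dE_mp2_lis = d$dE_mp2_lis,
               n_atoms_ed = d$n_atoms_ed, n_ao_ed = d$n_ao_ed,
               n_occ_lis = d$n_occ_lis, n_vir_lis = d$n_vir_lis,
               n_naf = d$n_naf, cc_niter = d$cc_niter)))
  e_dist <- sum(pairlist$pairs$epair[pairlist$pairs$classification == "distant"])
  E_corr <- sum(tab$dE_ccsd) + sum(tab$dE_t) +
    sum(tab$dE_mp2_ed) - sum(tab$dE_mp2_lis) + e_dist
  E_lmp2 <- sum(tab$dE_mp2_ed) + e_dist
  structure(list(per_lmo = tab, distant_pair_energy = e_dist,
                 E_corr = E_corr, E_lmp2 = E_lmp2,
                 E_scf = ref$scf_energy, E_total = ref$scf_energy + E_corr,
                 n_strong = sum(pairlist$pairs$classification == "strong"),
                 n_distant = sum(pairlist$pairs$classification == "distant")),
            class = "lnocc_report")
}

#' @export
print.lnocc_report <- function(x, ...) {
  cat("LNO-CCSD(T) energy report\n")
  cat(sprintf("  reference energy      %18.10f Eh\n", x$E_scf))
  cat(sprintf("  correlation energy    %18.10f Eh\n", x$E_corr))
  cat(sprintf("  total energy          %18.10f Eh\n", x$E_total))
  cat(sprintf("  local MP2 correlation %18.10f Eh\n", x$E_lmp2))
  cat(sprintf("  distant pair energy   %18.10f Eh (%d pairs; %d strong)\n",
              x$distant_pair_energy, x$n_distant, x$n_strong))
  cat(sprintf("  domains: %d (%d spin-averaged)\n", nrow(x$per_lmo),
              sum(x$per_lmo$path == "spin_averaged")))
  invisible(x)
}

#' Run the full LNO-CCSD(T) pipeline
#'
#' Reference determinant, restricted Boys localization, PAO/pair
#' machinery, per-LMO extended domains, LNO compression and LIS
#' CCSD(T), assembled into the total correlation energy.
#'
#' @param mol molecule object.
#' @param basis basis-set name.
#' @param config configuration from [lnocc_config()].
#' @param mode SCF mode (\code{"rohf"} or \code{"uhf_qro"}).
#' @param verbose print per-domain progress.
#' @param ref optional pre-built reference state (avoids repeating the
#'   SCF when the same molecule is run under several configurations).
#' @return \code{lnocc_report}.
#' @export
lnocc_energy <- function(mol, basis = "sto-3g", config = lnocc_config(),
                         mode = "rohf", verbose = FALSE, ref = NULL) {
  if (is.null(ref)) ref <- build_reference(mol, basis, mode = mode)
  lmos <- localize_boys_restricted(ref)
  paos <- build_paos(ref, lmos)
  if (verbose) message("reference E = ", sprintf("%.10f", ref$scf_energy),
                       " Eh; ", ncol(lmos$C), " correlated LMOs")
  pds <- lapply(seq_len(ncol(lmos$C)), build_primary_domain,
                ref = ref, lmos = lmos, paos = paos,
                T_PDo = config$T_PDo, T_PDv = config$T_PDv,
                orth_tol = config$orth_tol)
  pairlist <- classify_pairs(ref, lmos, paos, pds,
                             eps_w = config$eps_w, g_w = config$g_w,
                             h_w = config$h_w, f_w = config$f_w,
                             mode = config$pair_energy_mode,
                             T_PDo = config$T_PDo)
  fods <- build_fock_offdiagonal(ref)
  domains <- lapply(seq_len(ncol(lmos$C)), .run_domain,
                    ref = ref, lmos = lmos, paos = paos,
                    pairlist = pairlist, config = config, fods = fods,
                    verbose = verbose)
  rep <- assemble_energy(domains, pairlist, ref)
  rep$config <- config
  rep$molecule <- mol$name
  rep$basis <- if (is.character(basis)) basis else attr(basis, "name")
  rep
}

#' Canonical CCSD(T) oracle on the full molecule
#'
#' Brute-force density-fitted canonical CCSD(T) (semicanonical
#' unrestricted basis, frozen cores excluded, explicit triples
#' denominators), with the per-occupied-orbital CCSD partition.
#'
#' @param ref reference state.
#' @param max_spin_orbitals refusal guard for the full-space solver.
#' @return \code{lnocc_oracle} result with MP2, CCSD, (T) and total
#'   correlation energies.
#' @export
canonical_ccsdt_oracle <- function(ref, max_spin_orbitals = 250) {
  sys <- oracle_so_system(ref)
  nso <- sys$no + sys$nv
  if (nso > max_spin_orbitals)
    stop("system too large for the canonical oracle: ", nso,
         " spin orbitals (cap ", max_spin_orbitals, ")")
  mp2 <- oracle_mp2(ref)
  cc <- oracle_ccsd(sys)
  et <- oracle_triples(sys, cc)
  structure(list(E_mp2 = mp2$E_corr, E_ccsd = cc$energy, E_t = et,
                 E_corr = cc$energy + et,
                 E_total = ref$scf_energy + cc$energy + et,
                 partition = diag(ccsd_energy_matrix(sys, cc)),
                 niter = cc$niter, n_spin_orbitals = nso),
            class = "lnocc_oracle")
}

#' Write an oracle result to JSON
#' @param oracle \code{lnocc_oracle} from [canonical_ccsdt_oracle()].
#' @param path output file.
#' @export
write_oracle_json <- function(oracle, path) {
  jsonlite::write_json(list(E_mp2 = oracle$E_mp2, E_ccsd = oracle$E_ccsd,
                            E_t = oracle$E_t, E_corr = oracle$E_corr,
                            E_total = oracle$E_total,
                            n_spin_orbitals = oracle$n_spin_orbitals),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.lnocc_oracle <- function(x, ...) {
  cat("canonical oracle:", x$n_spin_orbitals, "spin orbitals\n")
  cat(sprintf("  E_MP2  %16.10f\n  E_CCSD %16.10f\n  E_(T)  %16.10f\n  E_corr %16.10f\n",
              x$E_mp2, x$E_ccsd, x$E_t, x$E_corr))
  invisible(x)
}

#' Write an energy report to JSON
#'
#' @param report \code{lnocc_report}.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  out <- list(schema = "lnocc-report-1",
              molecule = report$molecule, basis = report$basis,
              E_scf = report$E_scf, E_corr = report$E_corr,
              E_total = report$E_total, E_lmp2 = report$E_lmp2,
              distant_pair_energy = report$distant_pair_energy,
              n_strong = report$n_strong, n_distant = report$n_distant,
              per_lmo = report$per_lmo)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-domain table to CSV
#' @param report \code{lnocc_report}.
#' @param path output file.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$per_lmo, path, row.names = FALSE)
  invisible(path)
}
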