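# Threshold configuration: presets mirror the method's published
# defaults ("normal"), a one-decade-tightened variant ("tight"), and a
# truncation-free limit ("none") used for canonical-limit validation.

#' Threshold configuration for an LNO-CCSD(T) run
#'
#' @param preset \code{"normal"}, \code{"tight"} or \code{"none"}.
#' @param ... named overrides of individual fields.
#' @return an \code{lnocc_config} list with fields:
#'   \describe{
#'     \item{eps_o, eps_v}{occupied/virtual LNO occupation thresholds}
#'     \item{eps_w}{strong-pair energy threshold (hartree)}
#'     \item{T_EDo, T_PDo, T_PDv, T_0}{BP completeness thresholds}
#'     \item{eps_naf}{natural-auxiliary-function threshold (hartree)}
#'     \item{T_LT}{Laplace quadrature relative-error tolerance}
#'     \item{g_w, h_w, f_w}{pair-classification extension parameters}
#'     \item{spin_polarization_approx}{use the spin-averaged path for
#'       SOMO-free domains}
#'     \item{pair_energy_mode}{\code{"multipole"} or \code{"exact_pd"}}
#'   }
#' @export
lnocc_config <- function(preset = c("normal", "tight", "none"), ...) {
  preset <- match.arg(preset)
  cfg <- list(eps_o = 1e-5, eps_v = 1e-6, eps_w = 1e-5,
              T_EDo = 0.9999, T_PDo = 0.999, T_PDv = 0.98, T_0 = 0.985,
              eps_naf = 1e-2, T_LT = 1e-2, g_w = 5, h_w = 50,
              f_w = c(dd = 1, ds = 0.5, ss = 0.25),
              spin_polarization_approx = FALSE,
              pair_energy_mode = "multipole",
              orth_tol = 1e-7, cc_conv = 1e-8, cc_maxiter = 100,
              preset = preset)
  if (preset == "tight") {
    cfg$eps_o <- 1e-6; cfg$eps_v <- 1e-7; cfg$eps_w <- 1e-6
  } else if (preset == "none") {
    cfg$eps_o <- 0; cfg$eps_v <- 0; cfg$eps_w <- 0; cfg$eps_naf <- 0
    cfg$T_EDo <- 1; cfg$T_PDo <- 1; cfg$T_PDv <- 1; cfg$T_0 <- 1
    cfg$T_LT <- 1e-7
    cfg$pair_energy_mode <- "exact_pd"
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "lnocc_config")
}

#' Read a threshold configuration from YAML
#'
#' Accepts the flat keyword namespace (\code{lnoepso}, \code{lnoepsv},
#' \code{wpairtol}, \code{bpedo}, \code{naf_cor}, \code{laptol},
#' \code{epairscale}, \code{epairestfact}) plus the package-specific
#' keys (\code{preset}, \code{spin_polarization_approx},
#' \code{pair_energy_mode}, \code{f_w_dd}, \code{f_w_ds}, \code{f_w_ss}).
#'
#' @param path YAML file.
#' @return an \code{lnocc_config}.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  keymap <- c(lnoepso = "eps_o", lnoepsv = "eps_v", wpairtol = "eps_w",
              bpedo = "T_EDo", naf_cor = "eps_naf", laptol = "T_LT",
              epairscale = "g_w", epairestfact = "h_w")
  args <- list(preset = if (!is.null(y$preset)) y$preset else "normal")
  for (k in names(y)) {
    if (k == "preset") next
    if (k %in% names(keymap)) args[[keymap[[k]]]] <- y[[k]]
    else if (k %in% c("spin_polarization_approx", "pair_energy_mode",
                      "T_PDo", "T_PDv", "T_0", "cc_conv", "cc_maxiter"))
      args[[k]] <- y[[k]]
    else if (k == "f_w_dd") args$f_w <- NULL  # handled below
  }
  cfg <- do.call(lnocc_config, args)
  for (cl in c("dd", "ds", "ss")) {
    kk <- paste0("f_w_", cl)
    if (!is.null(y[[kk]])) cfg$f_w[[cl]] <- y[[kk]]
  }
  cfg
}

#' @export
print.lnocc_config <- function(x, ...) {
  cat("<config preset:", x$preset, "> eps_o", x$eps_o, "eps_v", x$eps_v,
      "eps_w", x$eps_w, "T_EDo", x$T_EDo, "eps_naf", x$eps_naf,
      "T_LT", x$T_LT, "\n  g_w", x$g_w, "h_w", x$h_w,
      "f_w", paste(names(x$f_w), x$f_w, sep = "=", collapse = " "),
      "spin-pol", x$spin_polarization_approx,
      "pairs", x$pair_energy_mode, "\n")
  invisible(x)
}
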