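#' @useDynLib lnocc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ANGSTROM_TO_BOHR <- 1.8897259886

#' Load a Gaussian basis set by name
#'
#' Basis sets are stored as plain-text tables under
#' \code{inst/extdata/basis}. Shipped sets: \code{"sto-3g"} and
#' \code{"6-31g"} for H, C, N and O. Cartesian components are used
#' throughout (6d ordering).
#'
#' @param name basis-set name, case insensitive (e.g. \code{"sto-3g"}).
#' @return a named list per element; each element holds a list of shells
#'   with fields \code{l}, \code{exps}, \code{coefs}.
#' @export
load_basis <- function(name) {
  fname <- system.file("extdata", "basis",
                       paste0(tolower(name), ".txt"), package = "lnocc")
  if (!nzchar(fname)) stop("unknown basis set: ", name)
  lines <- readLines(fname)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  out <- list()
  i <- 1
  ltab <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    elem <- hdr[1]; typ <- toupper(hdr[2])
    i <- i + 1
    prim <- list()
    while (i <= length(lines) && grepl("^\\s*[0-9.+-]", lines[i])) {
      prim[[length(prim) + 1]] <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    pm <- do.call(rbind, prim)
    if (is.null(out[[elem]])) out[[elem]] <- list()
    if (typ == "SP") {
      out[[elem]][[length(out[[elem]]) + 1]] <- list(l = 0L, exps = pm[, 1], coefs = pm[, 2])
      out[[elem]][[length(out[[elem]]) + 1]] <- list(l = 1L, exps = pm[, 1], coefs = pm[, 3])
    } else {
      out[[elem]][[length(out[[elem]]) + 1]] <-
        list(l = ltab[[typ]], exps = pm[, 1], coefs = pm[, 2])
    }
  }
  attr(out, "name") <- tolower(name)
  out
}

#' Build the shell table of a molecule in a given basis
#'
#' @param mol molecule object from [read_xyz()] or [generate_fixture()].
#' @param basis a basis list from [load_basis()] or a basis-set name.
#' @return a shell table understood by the integral backend, with
#'   \code{nbf} attribute (number of cartesian basis functions) and
#'   per-function atom map \code{ao_atom}.
#' @export
build_shells <- function(mol, basis) {
  if (is.character(basis)) basis <- load_basis(basis)
  l <- integer(0); atom <- integer(0); exps <- list(); coefs <- list()
  centers <- NULL
  for (ia in seq_along(mol$atoms)) {
    el <- mol$atoms[ia]
    bs <- basis[[el]]
    if (is.null(bs)) stop("element ", el, " not in basis set ", attr(basis, "name"))
    for (shell in bs) {
      l <- c(l, shell$l)
      atom <- c(atom, ia - 1L)
      exps[[length(exps) + 1]] <- shell$exps
      coefs[[length(coefs) + 1]] <- shell$coefs
      centers <- rbind(centers, mol$coords_bohr[ia, ])
    }
  }
  ncart <- (l + 1L) * (l + 2L) / 2L
  ao_atom <- rep(atom + 1L, times = ncart)
  structure(list(l = l, atom = atom, centers = centers, exps = exps, coefs = coefs),
            nbf = sum(ncart), ao_atom = ao_atom, class = "lnocc_shells")
}

#' Generate an even-tempered auxiliary fitting basis
#'
#' Builds a per-element auxiliary basis from the orbital basis: for each
#' angular momentum up to twice the maximum occupied-orbital angular
#' momentum of the element, an even-tempered geometric progression of
#' primitives spans twice the primitive exponent range of the orbital
#' basis (the exponents of density products). This is the package's own
#' automatic fitting scheme; all density-fitting comparisons inside the
#' package use the same auxiliary set, so fitting errors cancel in
#' method-vs-oracle differences.
#'
#' @param basis orbital basis list from [load_basis()].
#' @param beta even-tempered progression ratio (default 2.5).
#' @param lmax_factor auxiliary maximum angular momentum factor (default 2).
#' @return a basis list in the same format as [load_basis()].
#' @export
autoaux_basis <- function(basis, beta = 2.5, lmax_factor = 2L,
                          prune_tol = 1e-6) {
  out <- list()
  for (el in names(basis)) {
    shells <- basis[[el]]
    lmax <- max(vapply(shells, function(s) s$l, integer(1)))
    aux <- list()
    # at least p functions even for s-only elements (H): products of an
    # s function with a p function on a neighbour carry p character
    laux_top <- max(lmax_factor * lmax, 1L)
    for (laux in 0:laux_top) {
      # exponent range of products of primitives that can carry this l
      cand <- unlist(lapply(shells, function(s) s$exps))
      amin <- 2 * min(cand); amax <- 2 * max(cand)
      # very diffuse core products are irrelevant above l=0; compress range
      if (laux > 0) amax <- amax / 4^laux
      amax <- max(amax, amin * 1.01)
      n <- max(2L, ceiling(log(amax / amin) / log(beta)) + 1L)
      e <- amin * beta^(seq_len(n) - 1)
      for (x in e) aux[[length(aux) + 1]] <- list(l = laux, exps = x, coefs = 1.0)
    }
    # pivoted-Cholesky pruning of the atomic Coulomb metric: an
    # even-tempered candidate set is strongly redundant, and redundant
    # directions are amplified by the metric whitening, polluting the
    # NAF spectrum; keep a well-conditioned subset
    if (prune_tol > 0) {
      tmp <- structure(list(l = vapply(aux, function(s) as.integer(s$l), 0L),
                            atom = rep(0L, length(aux)),
                            centers = matrix(0, length(aux), 3),
                            exps = lapply(aux, `[[`, "exps"),
                            coefs = lapply(aux, `[[`, "coefs")),
                       class = "lnocc_shells")
      ncart <- (vapply(aux, `[[`, 0, "l") + 1) * (vapply(aux, `[[`, 0, "l") + 2) / 2
      shell_of <- rep(seq_along(aux), times = ncart)
      V <- cpp_eri2c(tmp)
      ch <- suppressWarnings(chol(V, pivot = TRUE, tol = prune_tol * max(diag(V))))
      rank <- attr(ch, "rank")
      keep_fun <- attr(ch, "pivot")[seq_len(rank)]
      keep_shell <- sort(unique(shell_of[keep_fun]))
      aux <- aux[keep_shell]
    }
    out[[el]] <- aux
  }
  attr(out, "name") <- paste0(attr(basis, "name"), "-autoaux")
  out
}
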