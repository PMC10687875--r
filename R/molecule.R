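ELEMENT_Z <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
               O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L,
               Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L,
               Sc = 21L, Ti = 22L, V = 23L, Cr = 24L, Mn = 25L, Fe = 26L,
               Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L)

# frozen-core orbital counts per element; 3d metals freeze the subvalence
# (3s3p) shells as well.
frozen_core_count <- function(z) {
  if (z <= 2) 0L
  else if (z <= 10) 1L
  else if (z <= 18) 5L
  else if (z <= 30) 9L
  else stop("no frozen-core count tabulated for Z = ", z)
}

#' Construct a molecule object
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge total charge.
#' @param multiplicity spin multiplicity (2S+1).
#' @param name optional label.
#' @return an object of class \code{lnocc_molecule}.
#' @export
molecule <- function(atoms, coords, charge = 0L, multiplicity = 1L, name = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(atoms) == nrow(coords))
  z <- ELEMENT_Z[atoms]
  if (anyNA(z)) stop("unknown element(s): ", paste(atoms[is.na(z)], collapse = ", "))
  nelec <- sum(z) - charge
  nunp <- multiplicity - 1L
  if (multiplicity < 1L || nelec < nunp || (nelec - nunp) %% 2L != 0L)
    stop("charge/multiplicity incompatible with ", nelec, " electrons")
  structure(list(atoms = atoms, coords = coords,
                 coords_bohr = coords * ANGSTROM_TO_BOHR,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 z = unname(z), nelec = nelec, name = name),
            class = "lnocc_molecule")
}

#' @export
print.lnocc_molecule <- function(x, ...) {
  cat("<molecule", if (nzchar(x$name)) x$name else "", ">",
      length(x$atoms), "atoms, charge", x$charge,
      "multiplicity", x$multiplicity, "\n")
  invisible(x)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom count line, comment line, then element and
#' Cartesian coordinates in Angstrom.
#'
#' @param path file path.
#' @inheritParams molecule
#' @return an \code{lnocc_molecule}.
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  atoms <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(atoms, coords, charge, multiplicity, name = trimws(lines[2]))
}

#' Write a molecule to an XYZ file
#' @param mol molecule.
#' @param path output path.
#' @export
write_xyz <- function(mol, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(length(mol$atoms)), con)
  writeLines(mol$name, con)
  for (i in seq_along(mol$atoms))
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", mol$atoms[i],
                       mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3]), con)
  invisible(path)
}

nuclear_repulsion <- function(mol) {
  e <- 0
  n <- length(mol$atoms)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((mol$coords_bohr[i, ] - mol$coords_bohr[j, ])^2))
    e <- e + mol$z[i] * mol$z[j] / r
  }
  e
}

# --- fixture geometry helpers -------------------------------------------

TET <- 109.47122063449069 * pi / 180  # tetrahedral angle

# unit vector helpers for zig-zag chains
.chain_backbone <- function(n, cc = 1.54) {
  a <- TET / 2
  up <- c(sin(a), cos(a), 0); dn <- c(sin(a), -cos(a), 0)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)[-1])
    pos[i, ] <- pos[i - 1, ] + cc * (if (i %% 2 == 0) up else dn)
  pos
}

# two tetrahedral directions completing neighbors d1, d2
.tet_complete2 <- function(d1, d2) {
  e1 <- -(d1 + d2); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  e2 <- e2 / sqrt(sum(e2^2))
  c1 <- 1 / sqrt(3); s1 <- sqrt(2 / 3)
  list(e1 * c1 + e2 * s1, e1 * c1 - e2 * s1)
}

# three tetrahedral directions around single neighbor direction d1
.tet_complete3 <- function(d1, phase = 0) {
  p <- if (abs(d1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- p - sum(p * d1) * d1; p <- p / sqrt(sum(p^2))
  q <- c(d1[2] * p[3] - d1[3] * p[2],
         d1[3] * p[1] - d1[1] * p[3],
         d1[1] * p[2] - d1[2] * p[1])
  lapply(0:2, function(k) {
    ang <- phase + 2 * pi * k / 3
    -d1 / 3 + sqrt(8 / 9) * (cos(ang) * p + sin(ang) * q)
  })
}

#' Generate a fixture molecule
#'
#' Deterministic idealized geometries (C-C 1.54 A, C-H 1.09 A, O-H 0.97 A,
#' tetrahedral angles) used by the test-suite and examples. Radical chains
#' CnH(2n+1) carry the unpaired electron at a terminal CH2 site so that
#' locality of the spin density can be exercised; closed chains are the
#' corresponding alkanes.
#'
#' @param kind one of \code{"methyl"}, \code{"ethyl"}, \code{"hydroxyl"},
#'   \code{"water"}, \code{"water_cation"}, \code{"water_dimer"},
#'   \code{"radical_chain"}, \code{"closed_chain"}.
#' @param n chain length (number of carbons) for the chain kinds.
#' @return an \code{lnocc_molecule}.
#' @export
generate_fixture <- function(kind, n = 1L) {
  ch <- 1.09; oh <- 0.97
  if (kind == "methyl") kind <- "radical_chain"
  if (kind == "ethyl") { kind <- "radical_chain"; n <- 2L }
  switch(kind,
    hydroxyl = molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, oh)),
                        0L, 2L, name = "hydroxyl radical"),
    water = molecule(c("O", "H", "H"),
                     rbind(c(0, 0, 0),
                           c(oh * sin(52.26 * pi / 180), 0,  oh * cos(52.26 * pi / 180)),
                           c(-oh * sin(52.26 * pi / 180), 0, oh * cos(52.26 * pi / 180))),
                     0L, 1L, name = "water"),
    water_cation = {
      m <- generate_fixture("water")
      molecule(m$atoms, m$coords, 1L, 2L, name = "water cation")
    },
    water_dimer = {
      m <- generate_fixture("water")
      # donor-acceptor arrangement, O...O 2.98 A along x
      c2 <- m$coords; c2[, 1] <- c2[, 1] + 2.98
      molecule(c(m$atoms, m$atoms), rbind(m$coords, c2), 0L, 1L,
               name = "water dimer")
    },
    radical_chain = ,
    closed_chain = {
      stopifnot(n >= 1)
      cpos <- .chain_backbone(n)
      atoms <- rep("C", n); coords <- cpos
      addH <- function(coords, atoms, pos) {
        list(coords = rbind(coords, pos), atoms = c(atoms, "H"))
      }
      for (i in seq_len(n)) {
        nb <- list()
        if (i > 1) nb[[length(nb) + 1]] <- (cpos[i - 1, ] - cpos[i, ]) / 1.54
        if (i < n) nb[[length(nb) + 1]] <- (cpos[i + 1, ] - cpos[i, ]) / 1.54
        if (length(nb) == 2) {         # interior CH2
          dirs <- .tet_complete2(nb[[1]], nb[[2]])
          for (d in dirs) { r <- addH(coords, atoms, cpos[i, ] + ch * d); coords <- r$coords; atoms <- r$atoms }
        } else if (length(nb) == 1) {  # terminal
          dirs <- .tet_complete3(nb[[1]])
          nh <- if (kind == "radical_chain" && i == n) 2L else 3L
          for (d in dirs[seq_len(nh)]) { r <- addH(coords, atoms, cpos[i, ] + ch * d); coords <- r$coords; atoms <- r$atoms }
        } else {                       # n = 1: no carbon neighbors
          dirs <- c(.tet_complete3(c(0, 0, 1)), list(c(0, 0, 1)))
          nh <- if (kind == "radical_chain") 3L else 4L
          for (d in dirs[seq_len(nh)]) { r <- addH(coords, atoms, cpos[i, ] + ch * unlist(d)); coords <- r$coords; atoms <- r$atoms }
        }
      }
      mult <- if (kind == "radical_chain") 2L else 1L
      molecule(atoms, coords, 0L, mult,
               name = sprintf("%s C%d", kind, n))
    },
    stop("unknown fixture kind: ", kind)
  )
}
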