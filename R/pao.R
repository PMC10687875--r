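# Projected atomic orbitals, Boughton-Pulay atom lists, primary domains,
# multipole-approximated MP2 pair energies and the strong/distant pair
# classification.

#' Build restricted projected atomic orbitals
#'
#' Projects every occupied orbital (frozen cores, localized DOMOs and
#' SOMOs) out of each AO. The resulting PAOs span the spin-up virtual
#' space; the spin-down virtual space is spanned by the union of the
#' SOMOs and the PAOs. PAOs are normalized; near-null PAOs (norm below
#' \code{drop_tol} after projection) are flagged but kept.
#'
#' @param ref reference state.
#' @param lmos localized orbitals from [localize_boys_restricted()].
#' @param drop_tol flag threshold for near-null PAOs.
#' @return \code{lnocc_paoset} with normalized coefficients \code{C},
#'   \code{center_atom}, pre-normalization \code{norms}, \code{flagged}.
#' @export
build_paos <- function(ref, lmos, drop_tol = 1e-7) {
  S <- ref$ints$S
  n <- ref$ints$nbf
  Cocc <- cbind(ref$C[, ref$frozen_core_idx, drop = FALSE], lmos$C)
  Cp <- diag(n) - tcrossprod(Cocc) %*% S
  norms <- sqrt(pmax(diag(crossprod(Cp, S %*% Cp)), 0))
  flagged <- norms <= drop_tol
  Cn <- Cp
  for (k in which(!flagged)) Cn[, k] <- Cp[, k] / norms[k]
  structure(list(C = Cn, center_atom = attr(ref$ints$shells, "ao_atom"),
                 norms = norms, flagged = flagged),
            class = "lnocc_paoset")
}

#' Boughton-Pulay atom list of an orbital
#'
#' Greedy atom selection (descending Mulliken population) until the
#' overlap of the orbital with its projection onto the selected atoms'
#' AOs reaches the completeness threshold \code{T}.
#'
#' @param coef normalized AO coefficient vector of the orbital.
#' @param T completeness threshold in (0, 1].
#' @param ref reference state (supplies overlap and the AO-atom map).
#' @return list with \code{atoms} (ordered), \code{completeness},
#'   per-step completeness \code{trace}.
#' @export
bp_atom_list <- function(coef, T, ref) {
  if (!(T > 0 && T <= 1)) stop("BP completeness threshold must be in (0,1]")
  S <- ref$ints$S
  ao_atom <- attr(ref$ints$shells, "ao_atom")
  Sc <- as.vector(S %*% coef)
  pop <- vapply(seq_len(max(ao_atom)), function(a)
    sum(coef[ao_atom == a] * Sc[ao_atom == a]), 0)
  ord <- order(pop, decreasing = TRUE)
  sel <- integer(0); compl <- 0; trace <- numeric(0)
  for (a in ord) {
    sel <- c(sel, a)
    idx <- which(ao_atom %in% sel)
    Saa <- S[idx, idx, drop = FALSE]
    rhs <- Sc[idx]
    cA <- tryCatch(solve(Saa, rhs), error = function(e)
      qr.solve(Saa + diag(1e-12, length(idx)), rhs))
    compl <- sum(rhs * cA)
    trace <- c(trace, compl)
    if (compl >= T) break
  }
  list(atoms = sel, completeness = compl, trace = trace, T = T)
}

# orthonormal columns from truncating coefs to the AOs of `atoms`
.truncate_orbital <- function(coef, atoms, ao_atom) {
  out <- coef
  out[!(ao_atom %in% atoms)] <- 0
  out
}

#' Build the primary domain of one localized orbital
#'
#' The occupied subspace holds the single (projected, renormalized)
#' central LMO; the virtual subspace holds the PAOs centered on the
#' LMO's BP atoms (spin-up) plus, for spin-down, any SOMO whose
#' \code{T_PDv} BP list overlaps the LMO's BP list. All orbitals are
#' projected onto the PD's AOs, orthogonalized and semicanonicalized
#' per spin.
#'
#' @param central index of the central LMO in \code{lmos}.
#' @param ref,lmos,paos reference, LMO set, PAO set.
#' @param T_PDo,T_PDv BP completeness for LMOs and PAOs/SOMOs.
#' @param orth_tol canonical-orthogonalization drop tolerance.
#' @return \code{lnocc_pd} object.
#' @export
build_primary_domain <- function(central, ref, lmos, paos,
                                 T_PDo = 0.999, T_PDv = 0.98,
                                 orth_tol = 1e-7) {
  S <- ref$ints$S
  ao_atom <- attr(ref$ints$shells, "ao_atom")
  bp_lmo <- bp_atom_list(lmos$C[, central], T_PDo, ref)
  pao_idx <- which(paos$center_atom %in% bp_lmo$atoms & !paos$flagged)
  atoms <- bp_lmo$atoms
  for (p in pao_idx)
    atoms <- union(atoms, bp_atom_list(paos$C[, p], T_PDv, ref)$atoms)
  # SOMO admission to the spin-down virtual space
  somo_cols <- which(lmos$origin == "SOMO")
  somo_in <- integer(0)
  for (s in somo_cols) {
    if (s == central) next
    bps <- bp_atom_list(lmos$C[, s], T_PDv, ref)
    if (length(intersect(bps$atoms, bp_lmo$atoms)) > 0) {
      somo_in <- c(somo_in, s)
      atoms <- union(atoms, bps$atoms)
    }
  }
  atoms <- sort(atoms)
  ao <- which(ao_atom %in% atoms)
  Spd <- S[ao, ao, drop = FALSE]
  # occupied: truncated central LMO, renormalized
  occ <- lmos$C[ao, central]
  occ <- occ / sqrt(sum(occ * (Spd %*% occ)))
  # spin-up virtual: PAOs truncated to PD AOs, central projected out
  Vup <- paos$C[ao, pao_idx, drop = FALSE]
  proj <- function(M, O) M - O %*% (crossprod(O, Spd %*% M))
  Vup <- proj(Vup, matrix(occ, ncol = 1))
  Xup <- canonical_orth(crossprod(Vup, Spd %*% Vup), tol = orth_tol)
  Vup <- Vup %*% Xup
  if (ncol(Vup) == 0)
    stop("degenerate primary domain: empty spin-up virtual space for LMO ", central)
  fup <- ref$fock_up[ao, ao, drop = FALSE]
  fdn <- ref$fock_down[ao, ao, drop = FALSE]
  su <- semicanonicalize(Vup, fup)
  # spin-down virtual: admitted SOMOs first (exact), then PAOs
  Vdn_raw <- cbind(if (length(somo_in)) {
    m <- lmos$C[ao, somo_in, drop = FALSE]
    sweep(m, 2, sqrt(diag(crossprod(m, Spd %*% m))), "/")
  }, paos$C[ao, pao_idx, drop = FALSE])
  Vdn <- proj(Vdn_raw, matrix(occ, ncol = 1))
  Xdn <- canonical_orth(crossprod(Vdn, Spd %*% Vdn), tol = orth_tol)
  Vdn <- Vdn %*% Xdn
  sd <- semicanonicalize(Vdn, fdn)
  structure(list(central = central, atoms = atoms, ao = ao,
                 bp_atoms = bp_lmo$atoms,
                 occ = occ,
                 fkk_up = sum(occ * (fup %*% occ)),
                 fkk_dn = sum(occ * (fdn %*% occ)),
                 vir_up = su$C, eps_up = su$eps,
                 vir_dn = sd$C, eps_dn = sd$eps,
                 somo_in = somo_in),
            class = "lnocc_pd")
}

# transition multipole integrals (dipole, second and third central
# moments) between the PD-occupied LMO and each PD virtual, about the
# LMO centroid R
.mp_name <- function(p, q, r) {
  if (p + q + r == 0) return("s")
  paste0(strrep("x", p), strrep("y", q), strrep("z", r))
}

.pd_moments <- function(pd, ref, R, spin = c("up", "dn")) {
  spin <- match.arg(spin)
  V <- if (spin == "up") pd$vir_up else pd$vir_dn
  mp <- ref$ints$mp
  ao <- pd$ao
  k <- pd$occ
  g1 <- function(M) as.vector(crossprod(k, M[ao, ao, drop = FALSE] %*% V))
  raw <- list(s = g1(ref$ints$S))
  for (nm in c("x", "y", "z", "xx", "yy", "zz", "xy", "xz", "yz",
               "xxx", "yyy", "zzz", "xxy", "xxz", "xyy", "yyz",
               "xzz", "yzz", "xyz"))
    raw[[nm]] <- g1(mp[[nm]])
  # raw-name lookup by exponent triple (order of letters is canonical)
  look <- function(p, q, r) raw[[.mp_name(p, q, r)]]
  # central moment about R via the binomial shift
  cm <- function(p, q, r) {
    acc <- 0
    for (i in 0:p) for (j in 0:q) for (l in 0:r) {
      acc <- acc + choose(p, i) * choose(q, j) * choose(r, l) *
        (-R[1])^(p - i) * (-R[2])^(q - j) * (-R[3])^(r - l) * look(i, j, l)
    }
    acc
  }
  comps3 <- list(c(3,0,0), c(0,3,0), c(0,0,3), c(2,1,0), c(2,0,1),
                 c(1,2,0), c(0,2,1), c(1,0,2), c(0,1,2), c(1,1,1))
  M3 <- do.call(rbind, lapply(comps3, function(e) cm(e[1], e[2], e[3])))
  list(mu = rbind(cm(1,0,0), cm(0,1,0), cm(0,0,1)),
       M2 = rbind(cm(2,0,0), cm(0,2,0), cm(0,0,2),
                  cm(1,1,0), cm(1,0,1), cm(0,1,1)),
       M3 = M3)
}

# multipole interaction (k a | l b) for all (a, b): Taylor expansion of
# the Coulomb kernel about the centroids R1, R2 through fourth order
# (dipole-dipole, dipole-quadrupole, quadrupole-quadrupole and
# dipole-octupole terms).
.multipole_eri <- function(m1, m2, R1, R2) {
  Rv <- R2 - R1
  r <- sqrt(sum(Rv^2))
  H <- (3 * tcrossprod(Rv) / r^2 - diag(3)) / r^3
  # dip-dip: -mu1' H mu2
  dd <- -crossprod(m1$mu, H %*% m2$mu)
  # third derivative tensor g'''_abc of 1/|R+x| at x=0
  G <- array(0, c(3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    G[a, b, cc] <- -15 * Rv[a] * Rv[b] * Rv[cc] / r^7 +
      3 * ((a == b) * Rv[cc] + (a == cc) * Rv[b] + (b == cc) * Rv[a]) / r^5
  }
  # contract G with (M1 x mu2) and (mu1 x M2); M2 rows: xx yy zz xy xz yz
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  w2 <- c(1, 1, 1, 2, 2, 2)   # symmetric off-diagonal count
  dq <- matrix(0, ncol(m1$mu), ncol(m2$mu))
  for (p in 1:6) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    gv <- G[a, b, ]           # vector over c
    # 0.5 * [ M1_ab * (g . mu2) - (g . mu1) * M2_ab ]
    dq <- dq + 0.5 * w2[p] * (outer(m1$M2[p, ], as.vector(crossprod(gv, m2$mu))) -
                              outer(as.vector(crossprod(gv, m1$mu)), m2$M2[p, ]))
  }
  # fourth derivative tensor
  g4 <- function(a, b, cc, d) {
    105 * Rv[a] * Rv[b] * Rv[cc] * Rv[d] / r^9 -
      15 * ((a == b) * Rv[cc] * Rv[d] + (a == cc) * Rv[b] * Rv[d] +
            (a == d) * Rv[b] * Rv[cc] + (b == cc) * Rv[a] * Rv[d] +
            (b == d) * Rv[a] * Rv[cc] + (cc == d) * Rv[a] * Rv[b]) / r^7 +
      3 * ((a == b) * (cc == d) + (a == cc) * (b == d) +
           (a == d) * (b == cc)) / r^5
  }
  trip <- rbind(c(1,1,1), c(2,2,2), c(3,3,3), c(1,1,2), c(1,1,3),
                c(1,2,2), c(2,2,3), c(1,3,3), c(2,3,3), c(1,2,3))
  w3 <- c(1, 1, 1, 3, 3, 3, 3, 3, 3, 6)
  # quad-quad: (1/4) sum_{ab,cd} g4 M2_1[ab] M2_2[cd]
  G4q <- matrix(0, 6, 6)
  for (p in 1:6) for (q in 1:6)
    G4q[p, q] <- w2[p] * w2[q] *
      g4(pairs[p, 1], pairs[p, 2], pairs[q, 1], pairs[q, 2])
  qq <- 0.25 * crossprod(m1$M2, G4q %*% m2$M2)
  # dip-oct: -(1/6) [ mu1 . g4 . M3_2 + M3_1 . g4 . mu2 ]
  B <- matrix(0, 3, 10)
  for (a in 1:3) for (t in 1:10)
    B[a, t] <- w3[t] * g4(a, trip[t, 1], trip[t, 2], trip[t, 3])
  do <- -(1 / 6) * (crossprod(m1$mu, B %*% m2$M3) +
                    crossprod(m1$M3, t(B) %*% m2$mu))
  dd + dq + qq + do
}

#' Multipole-approximated MP2 pair energy of an LMO pair
#'
#' Evaluates the MP2-like pair energy with multipole-expanded ERIs
#' (dipole-dipole and dipole-quadrupole terms) between the transition
#' densities of the two primary domains, summed over the spin cases
#' allowed by the LMO occupations, with pseudocanonical virtual energies
#' and diagonal occupied Fock elements in the denominator.
#'
#' @param k,l LMO indices.
#' @param pds list of primary domains (index-aligned with LMOs).
#' @param ref,lmos reference and LMO set.
#' @return pair energy in hartree (non-positive).
#' @export
multipole_pair_energy <- function(k, l, pds, ref, lmos) {
  cen <- lmo_centroids(lmos, ref$ints$mp)
  R1 <- cen[k, ]; R2 <- cen[l, ]
  spins_k <- if (lmos$occupation[k] == 2L) c("up", "dn") else "up"
  spins_l <- if (lmos$occupation[l] == 2L) c("up", "dn") else "up"
  e <- 0
  for (sk in spins_k) for (sl in spins_l) {
    m1 <- .pd_moments(pds[[k]], ref, R1, sk)
    m2 <- .pd_moments(pds[[l]], ref, R2, sl)
    g <- .multipole_eri(m1, m2, R1, R2)
    ea <- if (sk == "up") pds[[k]]$eps_up else pds[[k]]$eps_dn
    eb <- if (sl == "up") pds[[l]]$eps_up else pds[[l]]$eps_dn
    fk <- if (sk == "up") pds[[k]]$fkk_up else pds[[k]]$fkk_dn
    fl <- if (sl == "up") pds[[l]]$fkk_up else pds[[l]]$fkk_dn
    D <- outer(ea, eb, "+") - fk - fl
    if (any(D <= 1e-8))
      stop("vanishing MP2 denominator in pair (", k, ",", l, "): min D = ",
           signif(min(D), 3))
    e <- e - sum(g^2 / D)
  }
  e
}

#' Exact-ERI pair energy in the union pair domain
#'
#' Builds the union of the two primary domains, orthonormalizes the
#' occupied pair and a shared virtual space per spin, transforms exact
#' density-fitted ERIs and evaluates the semicanonical MP2 pair energy
#' (including same-spin exchange).
#'
#' @inheritParams multipole_pair_energy
#' @param paos PAO set.
#' @return pair energy in hartree.
#' @export
exact_pd_pair_energy <- function(k, l, pds, ref, lmos, paos) {
  S <- ref$ints$S
  ao_atom <- attr(ref$ints$shells, "ao_atom")
  atoms <- sort(union(pds[[k]]$atoms, pds[[l]]$atoms))
  ao <- which(ao_atom %in% atoms)
  Spd <- S[ao, ao, drop = FALSE]
  occ_raw <- lmos$C[ao, c(k, l), drop = FALSE]
  # Lowdin among the two projected LMOs
  occ <- occ_raw %*% lowdin(crossprod(occ_raw, Spd %*% occ_raw))
  pao_idx <- which(paos$center_atom %in% atoms & !paos$flagged)
  proj <- function(M, O) M - O %*% (crossprod(O, Spd %*% M))
  fup <- ref$fock_up[ao, ao, drop = FALSE]
  fdn <- ref$fock_down[ao, ao, drop = FALSE]
  somo_in <- union(pds[[k]]$somo_in, pds[[l]]$somo_in)
  somo_in <- setdiff(somo_in, c(k, l))
  mk_virt <- function(extra_cols) {
    V <- cbind(if (length(extra_cols)) lmos$C[ao, extra_cols, drop = FALSE],
               paos$C[ao, pao_idx, drop = FALSE])
    V <- proj(V, occ)
    V %*% canonical_orth(crossprod(V, Spd %*% V), tol = 1e-7)
  }
  Vup <- mk_virt(integer(0)); su <- semicanonicalize(Vup, fup)
  Vdn <- mk_virt(somo_in);    sd <- semicanonicalize(Vdn, fdn)
  # DF tensors restricted to the pair-domain AOs (full auxiliary set:
  # "exact ERI" means exact within the global density fitting)
  B <- ref$df$B[ao, ao, , drop = FALSE]
  fkk <- c(up = sum(occ[, 1] * (fup %*% occ[, 1])),
           dn = sum(occ[, 1] * (fdn %*% occ[, 1])))
  fll <- c(up = sum(occ[, 2] * (fup %*% occ[, 2])),
           dn = sum(occ[, 2] * (fdn %*% occ[, 2])))
  spins_k <- if (lmos$occupation[k] == 2L) c("up", "dn") else "up"
  spins_l <- if (lmos$occupation[l] == 2L) c("up", "dn") else "up"
  e <- 0
  Bk <- list(up = df_transform(B, occ[, 1, drop = FALSE], su$C),
             dn = df_transform(B, occ[, 1, drop = FALSE], sd$C))
  Bl <- list(up = df_transform(B, occ[, 2, drop = FALSE], su$C),
             dn = df_transform(B, occ[, 2, drop = FALSE], sd$C))
  eps <- list(up = su$eps, dn = sd$eps)
  for (sk in spins_k) for (sl in spins_l) {
    ga <- matrix(Bk[[sk]][1, , ], dim(Bk[[sk]])[2])
    gb <- matrix(Bl[[sl]][1, , ], dim(Bl[[sl]])[2])
    g <- tcrossprod(ga, gb)                  # (k a | l b)
    D <- outer(eps[[sk]], eps[[sl]], "+") - fkk[[sk]] - fll[[sl]]
    if (sk == sl) {
      gx <- tcrossprod(matrix(Bl[[sl]][1, , ], dim(Bl[[sl]])[2]),
                       matrix(Bk[[sk]][1, , ], dim(Bk[[sk]])[2]))  # (l a | k b)
      e <- e - 0.5 * sum((g - t(gx))^2 / D)
    } else {
      e <- e - sum(g^2 / D)
    }
  }
  e
}

#' Classify LMO pairs as strong or distant
#'
#' A pair is strong when its estimated pair energy magnitude reaches
#' \eqn{f_w \epsilon_w}; borderline distant pairs (within a factor
#' \eqn{g_w}) are promoted when the Mulliken-overlap measure M of the
#' BP-truncated LMOs is at least \eqn{h_w |\epsilon_{pair}| / f_w}.
#'
#' @param ref,lmos,paos,pds reference, LMOs, PAOs, primary domains.
#' @param eps_w strong-pair threshold (hartree).
#' @param g_w borderline window factor.
#' @param h_w promotion factor (1/hartree).
#' @param f_w named occupation-class factors.
#' @param mode \code{"multipole"} or \code{"exact_pd"} pair energies.
#' @param T_PDo BP threshold for the truncated-LMO Mulliken charges.
#' @return \code{lnocc_pairlist}: data frame of pairs with energies,
#'   spin class, f_w, M (where evaluated) and classification.
#' @export
classify_pairs <- function(ref, lmos, paos, pds, eps_w = 1e-5,
                           g_w = 5, h_w = 50,
                           f_w = c(dd = 1, ds = 0.5, ss = 0.25),
                           mode = c("multipole", "exact_pd"),
                           T_PDo = 0.999) {
  mode <- match.arg(mode)
  nl <- ncol(lmos$C)
  rows <- list()
  ao_atom <- attr(ref$ints$shells, "ao_atom")
  S <- ref$ints$S
  # truncated-LMO Mulliken charges on BP atoms
  mull <- lapply(seq_len(nl), function(i) {
    bp <- bp_atom_list(lmos$C[, i], T_PDo, ref)
    ao <- which(ao_atom %in% bp$atoms)
    ct <- lmos$C[ao, i]
    Sc <- S[ao, ao, drop = FALSE] %*% ct
    q <- vapply(bp$atoms, function(a)
      sum(ct[ao_atom[ao] == a] * Sc[ao_atom[ao] == a]), 0)
    stats::setNames(q, bp$atoms)
  })
  if (nl >= 2) for (k in 1:(nl - 1)) for (l in (k + 1):nl) {
    cls <- if (lmos$occupation[k] == 2L && lmos$occupation[l] == 2L) "dd"
           else if (lmos$occupation[k] == 1L && lmos$occupation[l] == 1L) "ss"
           else "ds"
    fw <- f_w[[cls]]
    e <- if (mode == "multipole") multipole_pair_energy(k, l, pds, ref, lmos)
         else exact_pd_pair_energy(k, l, pds, ref, lmos, paos)
    strong <- abs(e) >= fw * eps_w
    M <- NA_real_
    if (!strong && abs(e) >= fw * eps_w / g_w) {
      common <- intersect(names(mull[[k]]), names(mull[[l]]))
      M <- if (length(common)) sum(mull[[k]][common] * mull[[l]][common]) else 0
      if (M >= h_w * abs(e) / fw) strong <- TRUE
    }
    rows[[length(rows) + 1]] <-
      data.frame(k = k, l = l, spin_class = cls, f_w = fw, epair = e,
                 M = M, classification = if (strong) "strong" else "distant")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = integer(0), l = integer(0), spin_class = character(0),
               f_w = numeric(0), epair = numeric(0), M = numeric(0),
               classification = character(0))
  structure(list(pairs = out, eps_w = eps_w, g_w = g_w, h_w = h_w,
                 f_w = f_w, mode = mode),
            class = "lnocc_pairlist")
}

#' @export
print.lnocc_pairlist <- function(x, ...) {
  cat("<pairlist>", nrow(x$pairs), "pairs;",
      sum(x$pairs$classification == "strong"), "strong,",
      sum(x$pairs$classification == "distant"), "distant; distant sum",
      sprintf("%.3e", sum(x$pairs$epair[x$pairs$classification == "distant"])),
      "Eh\n")
  invisible(x)
}

#' Export the pair diagnostics table
#' @param pairlist pair list.
#' @param path CSV output path.
#' @export
write_pair_table <- function(pairlist, path) {
  utils::write.csv(pairlist$pairs, path, row.names = FALSE)
  invisible(path)
}
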