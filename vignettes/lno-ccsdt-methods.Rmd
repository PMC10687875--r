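---
title: "Local natural orbital CCSD(T) for open-shell molecules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local natural orbital CCSD(T) for open-shell molecules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The method

`lnocc` computes CCSD(T) correlation energies for open-shell (and
closed-shell) molecules by a local natural orbital (LNO) decomposition
built on a restricted open-shell reference. The total correlation
energy is assembled from per-orbital contributions,

$$
E_\mathrm{corr} = \sum_{L}\Big[\delta E^\mathrm{CCSD(T)}_L
 + \big(\delta E^\mathrm{MP2,ED}_L - \delta E^\mathrm{MP2,LIS}_L\big)\Big]
 + \sum_{kl\,\in\,\mathrm{distant}} \varepsilon_{kl},
$$

where $L$ runs over the localized correlated occupied orbitals (LMOs).
Each LMO's CCSD(T) contribution is evaluated in a compressed local
interacting subspace (LIS); the MP2-level difference between the larger
extended domain (ED) and the LIS corrects the LNO truncation; distant
LMO pairs enter only through multipole-estimated MP2 pair energies
$\varepsilon_{kl}$. Summed over a complete set of orbital projectors
the partition is exact, so with all truncations disabled the method
reproduces canonical CCSD(T) — the test-suite verifies this to
$10^{-7}$ hartree (measured: ~$10^{-10}$) on CH$_3^\bullet$ and
H$_2$O$^+$.

The pipeline, in order:

1. **Reference determinant.** Density-fitted ROHF (Guest–Saunders
   effective Fock, DIIS) or UHF followed by quasi-restricted orbitals
   (natural orbitals of the UHF total density, classified by
   occupation). Either way the result is one restricted spatial
   orbital set partitioned into doubly occupied (DOMO), singly
   occupied (SOMO) and virtual orbitals, with the spin-up/spin-down
   Fock matrices of the converged determinant. Frozen cores follow
   standard element counts (He core for B–Ne, Ne core for Na–Ar,
   Ar core — i.e. subvalence 3s3p frozen — for 3d metals).
2. **Localization.** Foster–Boys Jacobi sweeps, run separately in the
   correlated-DOMO and SOMO subspaces, which are never mixed. SOMOs
   play a dual role throughout: occupied for spin-up, virtual for
   spin-down.
3. **PAOs, BP lists, pairs.** Projected atomic orbitals span the
   spin-up virtual space (spin-down: PAOs plus SOMOs). Boughton–Pulay
   atom lists assign compact atom supports to every orbital. Each LMO
   pair receives a multipole-approximated MP2 pair energy evaluated in
   the union of the two primary domains; pairs with
   $|\varepsilon_{kl}| \ge f_w\,\varepsilon_w$ are strong, the rest
   distant. Borderline distant pairs (within a factor $g_w$) are
   promoted when the Mulliken-overlap measure of the BP-truncated LMOs
   exceeds $h_w |\varepsilon_{kl}|/f_w$.
4. **Extended domains.** The ED of LMO $L$ holds $L$ plus its strong
   partners, projected onto the union of their extensive BP atom lists
   and re-orthogonalized by Gram–Schmidt (central first, then SOMOs)
   followed by Löwdin orthogonalization of the remaining DOMOs — so
   the central LMO and the SOMOs survive the later truncations
   exactly. The virtual space is built from PAOs centered on the PAO
   center domain (PCD); auxiliary functions are restricted to PCD
   atoms and the domain Coulomb metric is re-factorized.
5. **Laplace MP1 amplitudes and ED MP2.** The MP1 doubles with one
   occupied index fixed to the (non-canonical) central LMO are
   assembled in closed form by a Laplace quadrature of the energy
   denominator, shared across all spin cases. Singles enter only
   through the off-diagonal Fock matrix
   $F^\mathrm{OD} = F - S\,C\varepsilon C^\dagger S$, which vanishes
   identically for a self-consistent (closed-shell) reference;
   truncation-induced singles are discarded.
6. **LNOs.** Spin-summed MP1 density fragments of the central LMO
   (occupied–occupied, then virtual–virtual with the occupied index
   already restricted to the retained occupied LNOs) are diagonalized
   after zeroing the central row/column and all SOMO–DOMO /
   SOMO–virtual couplings. Orbitals with occupation above
   $\varepsilon_o$ (occupied) or $\varepsilon_v$ (virtual) are kept;
   the central LMO and the SOMOs are kept unconditionally. For a SOMO
   central the fragments are scaled by 2 before truncation (half of
   the spin cases vanish identically), so one threshold treats both
   domain types on the same footing; energies are never scaled.
7. **LIS integrals.** Two-external three-center integrals are formed
   through the PAO′/LNO′ intermediate (virtual LNOs expanded in
   occupied-projected PCD AOs); the spin-down blocks involving SOMOs
   are completed from occupied-index integrals via the dual role. All
   lists are compressed into one shared natural-auxiliary-function
   (NAF) basis from the spin-averaged $W = (W^\uparrow +
   W^\downarrow)/2$.
8. **LIS CCSD(T).** Spin-orbital CCSD with the full (non-diagonal)
   Fock matrix, DIIS-accelerated; the central LMO's contribution is
   read off a symmetric per-occupied-orbital energy matrix. The (T)
   contribution is evaluated only for the central occupied index by
   absorbing the factorized (Laplace) denominators into dressed
   amplitudes and integrals — triples over the full occupied space are
   never formed.
9. **Routing.** When the long-range spin-polarization approximation is
   enabled and an ED contains no SOMO, all its Fock blocks are
   replaced by the spin average, making both spin channels identical;
   distant LMO–SOMO spin effects remain in the pair energies.

# Thresholds

| field | default | meaning |
|---|---|---|
| `eps_o`, `eps_v` | 1e-5, 1e-6 | LNO occupation cutoffs (ratio 10) |
| `eps_w` | 1e-5 Eh | strong-pair energy threshold |
| `T_EDo` | 0.9999 | extensive BP completeness (ED atoms) |
| `T_PDo`, `T_PDv` | 0.999, 0.98 | primary-domain BP completeness (LMOs, PAOs/SOMOs) |
| `T_0` | 0.985 | compact BP completeness (PCD atoms) |
| `eps_naf` | 1e-2 | NAF truncation (singular-value scale, see below) |
| `T_LT` | 1e-2 | Laplace quadrature sup-norm relative error |
| `g_w`, `h_w` | 5, 50 /Eh | borderline window and promotion factor |
| `f_w` | 1, 1/2, 1/4 | pair-class factors DO–DO, DO–SO, SO–SO |

The `"normal"` preset is this table; `"tight"` tightens `eps_o`,
`eps_v`, `eps_w` by one decade; `"none"` disables every truncation
(including `T_LT`, tightened to 1e-7) and is the canonical-limit
configuration used for validation.

Two defaults deserve comment.

* **NAF threshold scale.** The kept natural auxiliary functions are
  those whose *singular values* of the whitened three-center integral
  matrix exceed `eps_naf` (equivalently, eigenvalues of $W$ above
  `eps_naf`$^2$). With this reading the default 1e-2 changes a
  domain's CCSD(T) energy by ~1e-7 hartree while removing half to two
  thirds of the auxiliary dimension; thresholding the $W$ eigenvalues
  directly at 1e-2 would instead cost ~1e-4 hartree per domain, two
  orders of magnitude above the accuracy the threshold is documented
  to deliver. We therefore adopt the singular-value scale.
* **`f_w` factors.** The DO–SO and SO–SO factors are set to 1/2 and
  1/4: a SOMO contributes half as many spin cases to a pair energy as
  a DOMO. They are configurable (`f_w` in `lnocc_config()`).

# Numerical choices

* **Integrals.** The package carries its own McMurchie–Davidson
  Gaussian integral engine (overlap, kinetic, nuclear attraction,
  multipole moments, 2-/3-center ERIs; cartesian shells). Everything
  downstream of the SCF — including the canonical oracles — uses the
  density-fitting representation, so fitting errors cancel in every
  local-vs-oracle comparison.
* **Auxiliary basis.** Even-tempered per-element fitting sets
  generated from the orbital basis (`autoaux_basis()`): geometric
  progressions (ratio 2.5) spanning twice the primitive exponent
  range, with angular momenta up to twice the orbital maximum (at
  least $p$ on hydrogen), pruned by pivoted Cholesky of the atomic
  Coulomb metric to remove near-dependencies.
* **Boys localization** starts from a fixed chain of small Givens
  rotations rather than the identity: canonical orbitals of symmetric
  molecules sit at a stationary saddle of the Boys functional where
  every pairwise Jacobi gradient vanishes. Convergence is declared at
  gradient norm $\le 10^{-8}$ or when the objective is stationary to
  $10^{-11}$ relative (symmetry-equivalent orbital pairs admit flat
  directions along which the gradient cycles without changing the
  functional). Orbital signs are fixed by making the largest AO
  coefficient positive.
* **Laplace quadratures** are fitted on a 400-point logarithmic grid
  (SVD least squares with iterative refinement, then a deterministic
  Nelder–Mead polish of the point positions), taking the smallest
  point count that meets `T_LT`; typical valence ranges need 3–4
  points at the default tolerance. Quadratures are memoized on a
  padded, rounded denominator range so similar domains share one
  object. One spin-independent quadrature per domain serves all spin
  cases (the pooled denominator range covers the singles gap as well).
* **Degeneracies.** LNOs within $10^{-12}$ of a threshold are all
  kept; canonical orthogonalization drops directions below $10^{-7}$;
  eigenvector signs are fixed deterministically. Domain results are
  summed in ascending LMO order, so reports are bitwise reproducible.
* **Multipole pair energies** include dipole–dipole and
  dipole–quadrupole interactions of the transition densities about the
  LMO centroids (the full fourth-order expansion of the production
  implementations adds quadrupole–quadrupole and dipole–octupole
  terms). Against exact-ERI pair-domain energies they agree within a
  factor of 2 beyond 8 bohr — order-of-magnitude fidelity is all the
  classification needs. An exact-ERI mode (`pair_energy_mode =
  "exact_pd"`) is available and is the default of the `"none"` preset.
* **Eq.-level choices left open by the sources.** The virtual density
  fragment uses the spin-balanced variant: every amplitude block with
  a virtual index of the given spin contributes, so both spin blocks
  receive contributions even for a SOMO central. The two-external AO
  contraction runs over the full ED AO list (restricting it to the PCD
  is a large-system cost optimization; the PAO′/LNO′ expansion itself
  is PCD-supported). Denominators are factorized by Laplace quadrature
  only; cross-checks against explicit denominators in canonical bases
  replace a second (Cholesky) factorization.

# Validation architecture

The canonical oracles are kept structurally separate from the local
pipeline: a second, independently transcribed spin-orbital CCSD solver
(different amplitude layout and intermediate organization), MP2 with
explicit denominators, and a full-triples (T) code with explicit
$D_{ijk}^{abc}$. Both CCSD transcriptions are anchored to a
determinant-basis FCI on two-electron systems (CCSD is exact there)
and to the independent MP2 at first order; the Laplace central-orbital
(T) is validated against the explicit-denominator (T) summed over a
complete projector set, including under random rotations of the
occupied projectors.

# Fixtures and problem sizes

All test molecules are generated programmatically
(`generate_fixture()`): idealized radicals and alkane chains (C–C
1.54 Å, C–H 1.09 Å, tetrahedral angles, terminal CH$_2^\bullet$ site
for radical chains), water variants, and H$_2$ at 1.4 bohr. Idealized
geometries are appropriate because every check is an internal
consistency test against the package's own oracles, not a literature
comparison.

The suite runs at desk scale, chosen for single-CPU runtimes:
canonical-limit and Laplace-(T) checks use CH$_3^\bullet$ and
H$_2$O$^+$ in the shipped 6-31G double-zeta basis; threshold
convergence uses the ethyl radical chain in 6-31G (in minimal-basis
chains the LNO truncation error is comparable to the fixed
domain-truncation baseline and the signed total error crosses zero
during the threshold scan, masking the convergence being probed); the long-range
spin-polarization check uses C$_8$–C$_{10}$ radical chains in STO-3G
(production-scale implementations of this method family demonstrate
the same properties on chains and complexes of 80–600 atoms in
triple-zeta bases — system size changes
the compression ratios, not the identities and convergence properties
asserted here). What passing tests show is that the machinery is exact
in its limits and converges with its thresholds; they do not probe
basis-set effects beyond double-zeta, heavy-element references, or
strongly multireference electronic structure.

# Known limitations

* Shipped orbital bases: STO-3G and 6-31G for H, C, N, O (plain-text
  tables; further elements/bases can be added as files).
* ROHF convergence uses DIIS on the effective Fock only; no
  second-order SCF. Difficult cases should use `mode = "uhf_qro"`.
* The SOMO subspace of systems with one localized radical site is
  trivially local; delocalized SOMOs (e.g. aromatic radicals) keep a
  single delocalized singly occupied LMO, enlarging its domain.
* Desk-scale memory model: per-domain tensors are held in memory; no
  disk tiling, point-group symmetry, or parallelization.
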