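# lnocc — local natural orbital CCSD(T) for open-shell molecules

`lnocc` is an R implementation of the restricted open-shell local
natural orbital CCSD(T) method — "gold standard" coupled-cluster
correlation energies evaluated domain by domain instead of over the
whole molecule, so the cost of the expensive CCSD(T) step is governed
by local orbital spaces rather than system size. It is aimed at method
developers and students who want a complete, transparent, desk-scale
realization of the machinery that production local-correlation codes
implement at scale: every step from Gaussian integrals to the
perturbative triples is open R/C++ in this package.

## The method in brief

A restricted open-shell reference (ROHF, or quasi-restricted orbitals
from UHF) is Boys-localized with the doubly occupied (DOMO) and singly
occupied (SOMO) subspaces kept separate. The correlation energy is
assembled from per-LMO contributions

E_corr = Σ_L [ δE_L^CCSD(T) + ( δE_L^MP2(ED) − δE_L^MP2(LIS) ) ] + Σ_distant ε_kl

* δE_L^CCSD(T): CCSD(T) contribution of central LMO L, computed by a
  spin-orbital CCSD solver plus a Laplace-transform (T) evaluated only
  for the central occupied index, in a local interacting subspace
  (LIS) of natural orbitals built from MP1 density fragments;
* the MP2 difference between the extended domain (ED) and the LIS
  corrects the LNO truncation;
* distant pairs enter through multipole-estimated MP2 pair energies.

Domains are constructed from projected atomic orbitals and
Boughton–Pulay atom lists; three-center density-fitting integrals are
restricted to each domain and compressed by natural auxiliary
functions; SOMO-free domains can be routed through a spin-averaged
(closed-shell-like) path. With every truncation disabled the assembly
is exact: the test-suite verifies agreement with an independent
canonical CCSD(T) oracle to better than 1e-7 hartree.

See the methods vignette (`vignettes/lno-ccsdt-methods.Rmd`) for the
model, the thresholds and the design decisions.

## Worked example

Methyl radical in the shipped 6-31G basis at the default ("normal")
thresholds, against the package's canonical CCSD(T) oracle:

```r
library(lnocc)
mol <- generate_fixture("methyl")          # idealized CH3 radical, doublet
rep <- lnocc_energy(mol, "6-31g", lnocc_config("normal"))
print(rep)
#> LNO-CCSD(T) energy report
#>   reference energy          -39.5325811942 Eh
#>   correlation energy         -0.0970304093 Eh
#>   total energy              -39.6296116035 Eh
#>   local MP2 correlation      -0.0772137331 Eh
#>   distant pair energy         0.0000000000 Eh (0 pairs; 6 strong)
#>   domains: 4 (0 spin-averaged)

canonical_ccsdt_oracle(build_reference(mol, "6-31g"))
#> canonical oracle: 28 spin orbitals
#>   E_MP2     -0.0771570498
#>   E_CCSD    -0.0959323506
#>   E_(T)     -0.0010997821
#>   E_corr    -0.0970321327
```

The local correlation energy (−0.09703041 Eh) recovers 99.998% of the
canonical value (−0.09703213 Eh): on a molecule this small every pair
is strong and the domains span the whole system, so the residual
difference is pure LNO/NAF truncation. The per-domain table
(`rep$per_lmo`) lists each LMO's CCSD, (T) and MP2 contributions,
domain sizes and CCSD iteration counts; `write_report_json()` and
`write_report_csv()` export them.

A command-line entry point wraps the same pipeline:

```sh
Rscript exec/lnocc geometry.xyz --charge 0 --mult 2 --basis sto-3g \
        --preset normal --out report.json --csv domains.csv
```

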