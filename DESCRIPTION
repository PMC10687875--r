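Package: lnocc
Title: Local Natural Orbital CCSD(T) for Open-Shell Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Restricted open-shell local natural orbital (LNO) CCSD(T)
    correlation energies at desk scale. Builds a restricted open-shell
    Hartree-Fock (or quasi-restricted UHF) reference with an internal
    Gaussian integral engine, Boys-localizes the occupied space with
    doubly and singly occupied subspaces kept separate, constructs
    projected atomic orbitals, Boughton-Pulay domains and
    multipole-screened pair lists, evaluates density-fitted local MP2 in
    extended domains with Laplace-transform first-order amplitudes,
    compresses each domain with local natural orbitals and natural
    auxiliary functions, and solves spin-orbital CCSD plus a
    Laplace-transform perturbative triples correction in each local
    interacting subspace. Canonical density-fitted MP2/CCSD/(T) oracles
    and programmatic radical fixtures are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
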