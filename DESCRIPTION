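Package: scqedhf
Title: Strong-Coupling QED Hartree-Fock for Molecules in Optical Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mean-field electronic structure for a molecule coupled to a single
    quantized cavity photon mode (Pauli-Fierz Hamiltonian in the length gauge
    and dipole approximation). Implements strong-coupling QED Hartree-Fock
    (SC-QED-HF), in which orbital-specific coherent-state parameters dress the
    molecular orbitals with the photon field, together with three
    self-consistent-field drivers: a gradient-based DIIS baseline, a
    trust-region Newton-Raphson scheme with matrix-free Hessian linear
    transformations, and a hybrid scheme using direct inversion of the dense
    eta-eta Hessian block. Ships its own Gaussian AO-integral backend
    (McMurchie-Davidson), embedded benchmark geometries and basis sets, and an
    independent photon-Fock-space exact-diagonalization oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
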