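Package: rrcc3
Title: Rank-Reduced Equation-of-Motion Coupled-Cluster Triples (RR-EOM-CC3)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Computes singlet vertical excitation energies of closed-shell
    molecules with the rank-reduced equation-of-motion coupled-cluster method
    with approximate triple excitations (RR-EOM-CC3).  Ground- and
    excited-state triple-excitation amplitudes are compressed in the Tucker-3
    format; the factor matrices are obtained by higher-order orthogonal
    iteration (HOOI) over partially projected amplitude tensors with
    Laplace-separated orbital-energy denominators, and the compressed working
    equations are evaluated with density-fitted, T1-dressed two-electron
    integrals.  Includes closed-shell CCSD and block-Davidson EOM-CCSD stages,
    a dense canonical EOM-CC3 oracle and a sparse determinant-space full-CI
    reference for verification at small system sizes, an FCIDUMP reader and
    writer, a seeded synthetic Hamiltonian generator, and a rank-scan driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
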