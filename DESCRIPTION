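Package: ensrep
Title: Ensemble N-Representability Testing of Reduced Density Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether an alleged p-body reduced density matrix (p = 1, 2)
    of an N-electron system is pure or ensemble N-representable by adaptively
    growing a sequence of antihermitian excitation-deexcitation unitaries that
    evolve a (purified) statevector so as to minimize the squared
    Hilbert-Schmidt distance between its p-body reduced density matrix and the
    target. Ensemble representability is probed through a purification that
    embeds the ensemble in a doubled (system plus bath) orbital space with a
    particle-number-conserving operator pool. Includes exact fermionic
    statevector simulation over occupation-number sector bases, Coleman and
    Klyachko (generalized Pauli) audits of 1-RDM spectra, convex-mixture and
    canonical-ensemble thermal targets for minimal-basis H2 and H3 built from
    shipped FCIDUMP integrals, noise-perturbed targets, and a declarative
    scenario runner with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
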