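Package: pipfrag
Title: Fragmented Permutationally Invariant Polynomial Potential Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of permutationally invariant polynomial (PIP) bases in
    Morse variables by monomial symmetrization, fragmentation of large molecules
    into overlapping fragments with duplicate-polynomial elimination, joint linear
    least-squares fitting of electronic energies and Cartesian gradients, fast
    analytic gradients with per-atom sparsity branching, basis pruning and
    extension scored at the dataset maxima of the Morse variables, and harmonic
    vibrational analysis on the fitted surfaces. Includes a Burnside orbit-counting
    oracle, a surrogate potential generator for testing, dataset file I/O, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
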