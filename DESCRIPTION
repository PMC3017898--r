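Package: chebinvade
Title: Chebyshev Spectral Collocation Simulator for Tumour Invasion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-dimensional reaction-diffusion-haptotaxis models of
    tumour invasion and metastasis (tumour cells, extracellular matrix,
    matrix-degradative enzymes, and optionally endogenous inhibitors) by a
    Chebyshev spectral collocation method of lines. Boundary conditions
    (zero-flux or Dirichlet) are embedded directly into the differentiation
    operators, so accurate solutions are obtained on very small grids. The
    semidiscrete systems are advanced with adaptive stiff integrators from
    deSolve. Includes an independent second-order finite-volume reference
    solver, Clenshaw-Curtis mass diagnostics, barycentric interpolation,
    cluster-counting diagnostics for metastatic break-off, figure presets,
    a plain-text configuration format, and CSV snapshot output.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
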