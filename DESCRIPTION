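Package: noisecascade
Title: Cell-to-Cell Variability in Population-Averaged Characterization of
    Gene Network Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates steady-state transcriptional cascades whose modules are
    described by Hill transfer functions, applies multiplicative lognormal
    cell-to-cell noise (constant-CV or constant-VAR laws, with an optional
    correlated extrinsic component) at chosen network sites, and quantifies how
    population-averaged measurements distort nonlinear least-squares
    identification of module and black-box input-output transfer functions.
    Includes study drivers that reproduce module-characterization tables,
    sensitivity scans over gate parameters, extrinsic-noise sweeps, and
    prediction-versus-simulation comparisons for interconnected networks, all
    reproducible from seeded configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
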