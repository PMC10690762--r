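Package: ndes
Title: Nonlinear Difference Equation System Models of Forest Tree-Species
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and analyses a three-equation nonlinear difference equation
    system (NDES) describing the joint dynamics of pine, fir and broadleaf
    species-group abundance on the probability simplex, as observed in paired
    permanent forest-inventory plots remeasured on a five-year cycle. The
    package estimates the six model parameters from paired plot abundances by
    nonlinear least squares, projects composition forward by plot-wise
    iteration, locates the equilibrium (limit) composition as a fixed point of
    the map, and quantifies uncertainty of the limit via Monte Carlo
    propagation of the parameter covariance, truncated-normal interval
    estimation and a Hotelling-style F-test of extinction hypotheses. A
    synthetic-data module emulates the paired-plot inventory structure with
    known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
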