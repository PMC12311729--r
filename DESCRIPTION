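Package: edxkin
Title: Transient and Steady-State Kinetic Analysis of Extradiol
    Dioxygenase Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterization of catecholic
    substrates of extradiol ring-cleaving dioxygenases such as L-DOPA
    2,3-dioxygenase. Implements mass-action mechanism simulation of
    single-turnover stopped-flow traces with an enzyme-inactivation
    branch, nonlinear least-squares fitting of progress curves with
    profile-likelihood (FitSpace-style) confidence contours,
    Michaelis-Menten analysis in two parameterizations with specificity
    constants, spectrophotometric pKa determination from microplate
    titrations, Hammett linear free-energy regression, voltammetric
    summary arithmetic, and synthetic-data generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
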