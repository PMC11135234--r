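Package: uiknmf
Title: Optimal Rank Selection for Nonnegative Matrix Factorization via
    the Unit Invariant Knee
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonnegative matrix factorization (NMF) by multiplicative
    updates under Frobenius, Kullback-Leibler and nonsmooth objectives,
    with rank surveys (residual sum of squares and cophenetic-consensus
    curves over random restarts), automatic rank selection by locating
    the knee of the RSS curve with the unit-invariant-knee (extremum
    chord-distance) estimator, entry-holdout cross-validation (PRESS)
    as a comparator rank selector, and a simulator of mutational-process
    catalogs (96 trinucleotide-context mutation types, Poisson counts)
    with known ground-truth rank for self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
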