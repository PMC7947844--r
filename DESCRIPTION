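Package: logdater
Title: Dating Rooted Phylogenies by Log-Transformed Rate Smoothing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts rooted phylogenies with branch lengths in expected
    substitutions per site into time trees, given tip sampling dates and/or
    internal-node calibrations. Dating is formulated as constrained
    optimization over per-branch rate multipliers and a global clock rate:
    the default objective minimizes the weighted variance of log-transformed
    multipliers (symmetric penalties for rate increases and decreases), with
    the Poisson (Langley-Fitch) and least-squares objectives available in
    the same framework. Includes sparse linear calibration constraints,
    feasible multi-start initialization by root-to-tip regression and clade
    scaling, subsampling confidence intervals, and a simulation/evaluation
    toolkit: birth-death time trees with heterochronous sampling, strict and
    relaxed clock rate models, branch-length noise, Jukes-Cantor sequence
    simulation with fixed-topology maximum-likelihood branch length
    re-estimation, and standard accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Matrix,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
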