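Package: fitbench
Title: In Silico Benchmarking of Fitness Inference from Population Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward-time Wright-Fisher simulation of haploid populations of
    binary genomes evolving under a quadratic (additive plus pairwise
    epistatic) fitness function, with mutation, outcrossing recombination and
    multinomial drift.  Two independent schemes infer fitness parameters from
    the resulting time-stamped genotype samples: a transient
    quasi-linkage-equilibrium (tQLE) method that recovers Ising fields and
    couplings by naive mean field and maps them to selection coefficients, and
    a marginal path likelihood (MPL) method that solves a ridge-regularised
    linear system built from integrated allele-frequency covariances.
    Inference quality is scored by parameter recovery, genotype fitness rank
    order (including a top-5 percent elite criterion) and fitness-distribution
    decomposition with extreme-value fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
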