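Package: wfsel
Title: Likelihood Inference and Simulation for Time-Series Allele
    Frequency Data Under General Diploid Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for temporally sampled population-genetic data
    (ancient DNA time series, evolve-and-resequence experiments).
    Computes per-locus log-likelihoods of derived-allele count time
    series under a hidden Markov model whose hidden state is the
    population allele frequency evolving by the Wright-Fisher process
    with recurrent mutation and piece-wise constant general diploid
    selection, using Gaussian approximations of the per-generation
    frequency dynamics on a discretized frequency grid.  Provides
    maximum-likelihood estimation of selection coefficients on linear or
    geometric parameter grids with spline-interpolated off-grid
    estimates, chi-squared likelihood-ratio p-values, selection-onset
    estimation, Fisher's method for combining replicates, a discrete
    Wright-Fisher simulator of temporal samples with replicate
    filtering, readers for VCF (diploid and pseudo-haploid genotypes)
    and allele-count tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    optparse,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
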