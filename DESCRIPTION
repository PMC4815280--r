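Package: snpscan
Title: Integrated Allele Frequency, Allelic Imbalance, LOH and Copy Number
    Analysis for SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical methods for the integrated analysis of SNP-array
    hybridization intensities and genotype calls at the level of a single
    individual. Provides intensity preprocessing (log2 scaling, chip-effect
    removal, quantile normalization, aberrant-probe perturbation removal),
    individual-level allele-frequency estimation with a preferential
    hybridization correction and piecewise-linear recalibration against
    genotype cluster means, confidence-interval detectors for allelic
    imbalance, loss of heterozygosity / long contiguous stretches of
    homozygosity and copy-number gain or loss with Bonferroni-adjusted
    p-values, a sliding-window aberrant-proportion scan with LOESS smoothing
    and reference-quantile and hypothesis-test significance procedures,
    circular binary segmentation of the copy-number track together with a
    weighted quick variant restricted to regions of allelic imbalance or
    homozygosity, and a seeded synthetic-data generator and simulation study
    for false and true positive rate evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
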