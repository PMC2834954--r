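Package: CodingPotential
Title: Peak-Based Tests of Coding Potential in Short Pairwise Genomic
    Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether a short conserved pairwise genomic alignment
    contains protein-coding DNA. Aligned triplet pairs are scored with a
    codon-versus-background Markov log-odds model, windowed scores are
    smoothed by robust locally weighted regression (lowess), and the
    largest local maximum of the smoothed profile is used as a test
    statistic with an extreme-value p-value and FDR q-values. Includes
    AXT input, BED/TSV output, model training with pseudocounts, a
    null-model simulator, and null calibration, so the whole pipeline is
    testable without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, GenePrediction, Alignment, StatisticalMethod
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'alignment-io.R'
    'codon-model.R'
    'lod-scoring.R'
    'peak-test.R'
    'simulate.R'
    'pipeline.R'
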