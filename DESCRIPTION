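Package: polwaves
Title: Advancing and Clearing Pol II Wave Analysis for Spike-In Normalized
    PRO-seq Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of nascent-transcription (PRO-seq) time courses in
    which RNA polymerase II elongation is perturbed by rapid kinase
    inhibition. Reads strand-specific single-base 3' end coverage tracks
    with spike-in normalization, re-annotates transcription start sites
    from PRO-cap 5' end signal, filters genes for activity against an
    intergenic Poisson background and for upstream read-through, computes
    pausing indices, composite profiles and fold-change matrices, tests
    treated-versus-untreated region counts with a negative-binomial Wald
    test, calls advancing and clearing polymerase waves per gene with
    constrained three-state hidden Markov models, and converts wave-call
    series into elongation-rate estimates with bootstrap and per-gene
    uncertainty. Includes a kinematic two-population simulator of the
    post-inhibition polymerase density field so the whole pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
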