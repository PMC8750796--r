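Package: srnaland
Title: Small RNA Locus Classification, tRNA-Derived Small RNAs and Seed
    siRNA Target Prediction
Version: 0.1.0
Authors@R: person("srnaland", "developers", role = c("aut", "cre"),
    email = "srnaland@example.org")
Description: A small-RNA landscape analysis toolkit for plant genomes.
    Calls small RNA loci from aligned reads, classifies them with the
    80 percent DicerCall rule and modal read length, quantifies FPKM and
    applies expressed/novel/tissue-specific filters; builds mature (+CCA)
    and primary (40 bp flanked) tRNA references and identifies and
    classifies tRNA-derived small RNAs (tRF-5, tRF-3, tRF-1, 5tiR, 3tiR)
    by exact full-length matching; runs permutation overlap tests with
    z-scores and a null-normality gate; detects exceptionally highly
    expressed siren loci in endosperm; and predicts RdDM-style siRNA24
    target genes by integrating locus overlap, per-cytosine DNA
    methylation and mRNA expression. Ships a synthetic data generator
    with a planted ground-truth manifest so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
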