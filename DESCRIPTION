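Package: trophoRNA
Title: Placental Transcriptome Regulation Analysis Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics and filters for studying lineage-specific RNA
    regulation in the eutherian placenta. Implements RNAcompete-style 7-mer
    Z-score binding-preference summaries, competing splice-donor (TSS proxy)
    usage quantification from exon-exon junction counts, litter-aware
    permutation tests and within-litter normalization for placenta and
    embryo weights, 3'-seq polyadenylation-site calling with an
    internal-priming filter and regulated-pair selection, percent-spliced-in
    (PSI) differential-exon rules, and a tissue-enrichment screen for
    splicing factors. A synthetic-data module generates every input type
    with planted effects so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Transcriptomics, StatisticalMethod
RoxygenNote: 7.3.3
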