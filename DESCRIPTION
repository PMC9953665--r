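Package: txfuse
Title: Variant-Aware Isoform Quantification and Readthrough-Fusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for studying a two-gene locus with a
    readthrough fusion transcript. Builds transcript models from genome
    FASTA and GTF annotation, classifies variant consequences on
    transcripts (including NMD and nonstop decay prediction and HGVS
    stop-loss extension naming), quantifies isoform abundance with a
    lightweight k-mer equivalence-class EM estimator over
    haplotype-augmented references, measures allele fractions and
    two-variant phase from reads, designs and screens fusion junction
    probes, scores per-column conservation from multiple sequence
    alignments, maps variants onto inter-chain and metal-coordination
    contacts from atomic coordinates, and ships seeded simulators for
    every input so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
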