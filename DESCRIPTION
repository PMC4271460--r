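Package: dasbench
Title: Benchmarking Toolkit for Differential Alternative Splicing Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmarking framework for differential alternative
    splicing (DAS) detection methods. Provides a gene-model engine that parses
    GFF3/GTF annotation, flattens genes into disjoint exonic counting bins and
    exon-exon junctions, extracts and classifies splice events (skipped exon,
    intron retention, alternative donor/acceptor, mutually exclusive exons); a
    negative-binomial two-condition count simulator with controlled differential
    isoform proportions (PALT) and ground truth; reference count-based DAS
    detectors (variance-adjusted unit-fraction statistic with permutation
    p-values, Jensen-Shannon divergence on isoform proportions, percent-spliced-in
    bootstrap tests); and an evaluation harness computing restricted ROC curves,
    standardized partial AUC, recall and precision at an FDR cutoff, rank
    concordance and overlap tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
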