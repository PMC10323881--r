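Package: tfscout
Title: Transcription-Factor Target-Gene Prediction from Promoter Motif
    Scores and Pan-Cancer Expression Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts target genes of a transcription factor by combining
    two independent lines of evidence: sliding-window position weight
    matrix (PWM) scores over promoter sequences, summarised per gene as
    the best window score (k_max1), the sum of the three best window
    scores (k_max3) and the sum over all windows (k_total); and an
    expression R-score, the maximum Pearson correlation between the
    factor and each candidate gene taken across cancer-type sample
    groups. Includes readers for FASTA genomes, JASPAR-format count
    matrices, annotation/expression/peak tables, a ChIP-seq-derived
    reference-set builder with fold-enrichment filtering, set-based
    evaluation metrics (sensitivity, specificity, precision, P/C) with
    ROC/AUC threshold sweeps, and a seeded synthetic-benchmark generator
    with planted motifs and planted correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
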