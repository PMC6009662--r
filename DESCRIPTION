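Package: asnmd
Title: Alternative Splicing Events and Nonsense-Mediated Decay Target
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies alternative-splicing events between annotated
    transcript isoforms, extracts the structural and sequence features used
    to recognise nonsense-mediated decay (NMD) targets (premature
    termination codons under the 50-nt rule, 3' UTR splice junctions,
    upstream ORFs, exitrons, sequence motifs and k-mer composition,
    cytosine methylation at splice sites), performs event-level
    negative-binomial differential testing against NMD-deficient mutants
    with a two-mutant consensus rule, and trains an accuracy-filtered
    voting ensemble of classifiers that labels each event as an NMD target
    or not. Includes a synthetic-data generator that emulates the
    statistical structure of an NMD-inhibition RNA-seq study (multi-isoform
    genes with planted splicing events, negative-binomial counts, two
    mutant lines) with golden labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    caret,
    class,
    e1071,
    glmnet,
    jsonlite,
    methods,
    nnet,
    randomForest,
    ranger,
    rpart,
    rtracklayer,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    edgeR,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
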