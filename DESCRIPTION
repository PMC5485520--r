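Package: mirseek
Title: Small RNA-Seq miRNA Discovery, Differential Expression and Target
    Prediction for Stress-Response Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for plant microRNA analysis
    from small RNA sequencing libraries: adapter trimming and read collapsing
    into unique sequence tags, exact-match genome mapping with ncRNA triage,
    conserved miRNA assignment against a mature reference set, novel miRNA
    prediction by locus clustering, inverted-repeat dynamic programming,
    maximum weighted base-pair folding and stem-loop criteria evaluation,
    TPM normalization with an exact negative-binomial two-group count test,
    position-constrained miRNA target-site scanning of transcript sets, and
    stem-loop qRT-PCR 2^-ddCt relative quantification. A synthetic-data
    module generates genomes with planted pre-miRNA hairpins, negative
    binomial count matrices with condition-specific fold changes, and FASTQ
    libraries, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
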