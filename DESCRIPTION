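Package: miRVote
Title: Multi-Evidence MicroRNA Target Prioritization by Expression and
    Prediction Voting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate microRNA target genes by integrating
    several lines of evidence: calibrator-anchored down-regulation votes
    across independent transfection experiments, consensus votes from a
    panel of sequence-based target prediction tools, exact enrichment
    testing of predictions among top candidates, seed-complementary site
    scanning on annotated transcripts with nearest-neighbor duplex
    minimum-free-energy scoring, delta-delta-Ct relative quantification,
    and miRNA-target expression anticorrelation screening. Ships a
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneTarget, Sequencing, StatisticalMethod
RoxygenNote: 7.3.3
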