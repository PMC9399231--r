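Package: enhancerflow
Title: Enhancer Landscape Analysis for Shear-Stressed Endothelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used to
    map the endothelial enhancer landscape under laminar shear stress:
    negative-binomial Wald testing of differential chromatin accessibility,
    expression and transcription-factor binding; position-weight-matrix motif
    scanning with binomial enrichment; peak annotation and nearest-gene
    assignment; KLF4/BRG1 co-occupancy summaries; Activity-by-Contact (ABC)
    enhancer-to-gene prediction; HiChIP loop calling against a distance-decay
    background with loop classification and differential testing; and
    SNP-to-enhancer-to-gene mapping. A synthetic-data generator plants ground
    truth (differential regions, motifs, enhancer-gene links, loops) so every
    stage is testable end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
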