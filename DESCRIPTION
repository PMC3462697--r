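Package: mirnoise
Title: Small RNA-Seq miRNA Quantification and No-Replicate Differential
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for two-library small RNA sequencing experiments
    without biological replicates: FASTQ quality filtering and end
    trimming, read collapsing, contaminant screening, canonical miRNA
    annotation by exact 17-nucleotide seed matching with isoMIR merging,
    RPKM normalization with count-weighted effective lengths, and a
    simulation-based differential-expression statistic that ranks each
    miRNA's (M, D) signal against a noise cloud of simulated technical
    replicates. Includes a synthetic two-library generator with planted
    fold-changes for validation, volcano plots, and result tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
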