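Package: tnscreen
Title: Transposon Insertion Sequencing Analysis of Replication-Arrest
    Survival Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pooled transposon insertion sequencing
    (Tn-seq) fitness screens in which a mutant library is subjected to a
    transient replication arrest and allowed to recover. Implements
    per-position read filtering, inter-sample quantile normalization,
    gene-level aggregation over the 5-95% internal window,
    generation-matched log2 fold-change computation between treated and
    control libraries, and threshold-based classification of genes whose
    disruption is beneficial or detrimental to surviving the arrest. A
    companion simulator generates synthetic genomes, insertion libraries
    and treated/control count tables with planted per-gene survival and
    recovery effects, so the screen's operating characteristics
    (sensitivity, specificity, null calibration) can be measured end to
    end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
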