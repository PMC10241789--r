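Package: crestse
Title: Super-Enhancer Calling, Promoter Linking and Motif Discovery for
    Cranial Neural Crest Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a computational workflow for
    regulatory genomics of cranial neural crest cell (CNCC) subpopulations:
    ROSE-style super-enhancer calling from H3K27ac peak signal (promoter and
    blacklist filtering, 12.5 kb stitching, CPM quantification, hockey-stick
    cutoff, minimum-constituent rule), linking of super-enhancers to target
    gene promoters through promoter-capture Hi-C interaction scores, virtual
    4C viewpoint profiles and quantile-normalized interaction-change
    statistics between genotypes, accessibility-profile-driven transcription
    factor motif discovery (logCPM profile clustering, Pearson ranking into
    peak sets, Fisher/Benjamini-Hochberg motif enrichment, log-odds PWM
    scanning, similarity clustering and representative selection), and
    expression utilities (RPKM, delta-delta-Ct).  A synthetic-data module
    generates every pipeline input with planted ground truth so that each
    stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
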