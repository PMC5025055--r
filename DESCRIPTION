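Package: tritarget
Title: Triangulation of Transcription-Factor Targets from Knockdown
    RNA-Seq and Promoter ChIP Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying direct
    transcription-factor targets by triangulating basal two-group
    differential expression, paired knockdown differential expression,
    and input-normalized promoter ChIP signal. Provides CPM filtering
    and log-CPM location tests, signal-extraction-scaling (SES)
    ChIP/input normalization, TSS-window promoter scoring with binding
    tiers, consensus peak ranking, promoter motif-family enrichment
    with a per-family Bonferroni/median correction, exact association
    tests (Fisher, binomial sign, Wilcoxon), quadrant triangulation of
    basal versus knockdown fold changes, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
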