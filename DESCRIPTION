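Package: loopscape
Title: Architecture of Histone-Mark-Associated Chromatin Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistics for long-range chromatin loops detected by
    histone-mark-directed conformation capture (HiChIP): anchor-distance and
    TAD-crossing distributions with rank-sum comparisons, PRC2
    nucleation-point classification of loop anchors, windowed signal
    enrichment profiles at anchors, loess-smoothed overlap-versus-distance
    curves, virtual 4C extraction from binned contact matrices, loop-set
    concordance and cross-species conservation, pairwise 3D distance and
    contact-frequency analysis of chromatin-tracing (ORCA) data, and
    stratification of differential histone-signal sites by EZH2 occupancy
    and A/B compartment. Ships a seeded synthetic-data generator that
    emits every input format the pipeline consumes together with
    ground-truth manifests for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), GenomicRanges, IRanges, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
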