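Package: loopweaver
Title: Integration and Classification of Differential Chromatin Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating multi-resolution differential chromatin
    loop calls (Micro-C) with transcription-factor Hi-ChIP loops, ChIP peaks,
    TADs, chromatin-state segmentations, High-Affinity Sites and
    roX2-associated DNA-DNA loops.  Provides BEDPE pair-overlap algebra
    (either/ospan/both modes with bedtools-style slop), multi-resolution
    consensus loop merging, direct/indirect loop classification against
    Hi-ChIP evidence, chromatin-state and state-pair annotation,
    dosage-compensated gene association, aggregate peak analysis (APA) on
    binned contact matrices with central-pixel enrichment scoring, the
    enrichment and distribution statistics used throughout, and a seeded
    synthetic-data generator with recorded ground truth so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
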