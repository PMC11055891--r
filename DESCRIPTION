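Package: rdcscan
Title: Recurrent DNA Break Cluster Calling and
    Transcription-Replication Conflict Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Orientation-aware calling of recurrent DNA break clusters
    (RDCs) from LAM-HTGTS translocation junctions using a negative
    binomial island model, reconstruction of the DNA replication program
    from 16-fraction high-resolution Repli-seq (corrected S-phase
    fractions via BIRCH-style clustering, timing feature calling, and a
    fully convolutional termination-zone predictor trained on OK-seq
    derived labels), assembly of directional replication fork segments,
    and the downstream transcription-replication conflict statistics
    (head-on and co-directional DSB proportions, relative replication
    speed, relative DSB counts, and DNA:RNA hybrid stratification). A
    seeded synthetic-data generator with planted ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
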