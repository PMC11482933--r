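Package: epimodkit
Title: Multiplexed RNA Modification Mapping from Proximity-Barcoded Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative, simultaneous mapping of multiple RNA modifications
    (N6-methyladenosine and inosine) from proximity-barcoded enrichment
    sequencing libraries. Provides barcode (MBC/UMI) extraction and
    deduplication, spike-in based enrichment scaling, signal-versus-solution-
    control peak calling, reproducibility-driven false-positive modelling,
    native A-to-G pileup variant detection under inosine peaks, gene-model
    annotation with metagene and DRACH motif-shift profiles, differential
    comparison of peak landscapes, and a fully seeded synthetic library
    simulator that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
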