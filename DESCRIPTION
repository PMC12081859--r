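Package: camel
Title: CTCF Footprinting and Loop-Extrusion Analysis for MNase
    Proximity-Ligation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Base-pair-resolution detection of CTCF binding sites from
    MNase-based proximity-ligation experiments (MNase HiChIP, Region
    Capture Micro-C). Reconstructs exact digestion fragments from
    4DN-format pairs files, scores candidate positions with a multinomial
    quadrant statistic against an empirical null, classifies single-molecule
    footprints (nucleosome, CTCF, CTCF plus cohesin), and estimates
    cohesin loop-extrusion summaries: the fully-extruded (CTCF-CTCF) loop
    fraction, chromatin-context-stratified extruded loop sizes, contact
    probability curves, and a mixed-model cohesin effect. Includes a
    synthetic pairs simulator with ground-truth labels so every stage can
    be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
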