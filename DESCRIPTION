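Package: pccd
Title: Positive Cell Cluster Detection for Birth-Order Mapping of
    Transcription Factor Codes in Neural Lineages
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Positive Cell Cluster Detection (PCCD) pipeline
    for inferring which transcription factors are expressed at which birth
    ranks of a neural stem-cell lineage, starting from per-specimen 3D cell
    coordinates and binary immunostaining calls. Cells are ordered by their
    Euclidean distance from the neuroblast (a spatial proxy for birth
    order), per-rank expression frequencies are computed across specimens
    with censoring-aware bookkeeping, smoothed with a Savitzky-Golay
    filter, and positive-cell clusters are called under prominence-filtered
    peaks by an interpolated level-set descent that places a span of the
    observed mean cluster size. Cluster calls across factors assemble into
    a combinatorial per-rank code map that can be compared between
    genotypes. A synthetic-lineage generator with known ground truth makes
    every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Neuroscience, SingleCell, Spatial, Software
RoxygenNote: 7.3.3
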