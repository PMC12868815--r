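Package: lungspatial
Title: Spot Quality Control, Tissue Geometry and Spatial Organization
    Statistics for Visium Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for 10x Visium spatial transcriptomics
    sections of developing tissue. Implements eosin optical-density spot
    quality control (Beer-Lambert conversion, eigenvector stain estimation,
    reference normalization, per-spot quantile filtering), hexagonal-lattice
    tissue-edge and border geometry with peripheral-region annotation,
    per-spot-type Ripley's K/L point-pattern statistics with
    random-labeling envelopes and stage-level local-polynomial aggregation,
    composition and rank/permutation tests, pseudobulk aggregation and
    rank-based sex-signature scoring. Ships a synthetic Visium-like study
    generator (hex capture lattice, clustered categorical spot types,
    negative-binomial counts, rendered two-stain images) with known ground
    truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
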