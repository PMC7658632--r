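Package: mtospat
Title: Spatial Myeloid-T-Cell Distance and Overlap Analysis for Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial relationship between suppressive myeloid
    cells and cytotoxic T cells in annotated tumor tissue from per-cell
    coordinate exports. Implements the normalized global average distance
    (GAD_norm, a Clark-Evans style nearest-neighbour normalization), hexagonal
    hot-tile binning with the myeloid-T-cell overlap score (MTO), four-way
    patient stratification by CD8 density and MTO, and distance-derived gene
    signatures scored by rank-biserial single-sample enrichment with a
    random-signature permutation test. Ships a synthetic-cohort generator
    (Thomas cluster processes with shared parents, Gaussian-copula expression
    coupling) so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
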