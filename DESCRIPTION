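Package: stagescreen
Title: Stage-Specific Expression Screening of Developmental RPKM Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects genes specifically expressed at a reference developmental
    stage from a genes-by-samples RPKM matrix using a ratio-threshold filter:
    every sample outside the reference group must fall below a fixed fraction
    of the reference expression level, with a relaxed bound for stages adjacent
    to the reference. Developed around the Pacific oyster (Crassostrea gigas)
    pediveliger stage, where settlement and adhesive secretion occur, but
    applicable to any grouped expression matrix. Includes integration of
    candidate-gene annotations (functional groups, subcellular localization
    predictions, conserved-domain scan output), amino-acid composition
    profiling for collagen-likeness and cysteine richness, and a synthetic
    matrix generator with planted stage-specific genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
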