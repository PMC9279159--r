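Package: bridgemap
Title: Alignment-Free Cross-Species Coordinate Projection via Bridging
    Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects genomic coordinates between distantly related
    species without requiring a direct sequence alignment, by
    interpolating positions between collinear alignment anchors and
    optimizing the choice of intermediate ("bridging") species as a
    shortest-path problem over a species graph. Includes an
    exponential anchor-distance scoring function with a configurable
    distance half-life, classification of regulatory elements into
    directly conserved, indirectly conserved and non-conserved
    classes, cross-species comparison of binned epigenomic signal
    (quantile normalization, enrichment categories, capped log
    ratios, Fisher's exact enrichment tests), and a seeded synthetic
    synteny simulator that provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
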