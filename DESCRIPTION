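Package: mifTME
Title: Tumour Microenvironment Analysis for Multiplex Immunofluorescence
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale analysis of multiplex immunofluorescence (mIF)
    single-cell exports from solid-tumour sections, motivated by the tumour
    immune microenvironment of ALK-rearranged non-small cell lung cancer.
    Provides marker-based phenotyping of segmented cells into major immune
    populations (CD4/CD8 T cells, Tregs, exhausted CD8 T cells, B, NK,
    macrophages) and tumour cells; tumour/stroma compartmentalisation and
    invasive-margin banding from nest geometry; nearest-neighbour-distance
    and fixed-radius proximity metrics between tumour and immune cells;
    per-region composition summaries; the cohort statistical plan
    (Mann-Whitney comparisons, Spearman correlations, exact and chi-squared
    contingency tests, response rates); Kaplan-Meier, log-rank and Cox
    univariate-to-multivariate survival modelling with maximally selected
    log-rank cutpoints; and a synthetic-cohort generator that emulates the
    data structure so every stage is testable without access to patient
    material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
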