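Package: rootcue
Title: Curation and Differential Screening of Root Metabolomes as Herbivore Foraging Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for identifying root metabolites that
    guide foraging decisions of soil herbivores. Curates untargeted LC-MS
    feature tables (retention-time and mass-decimal exclusion, co-elution
    fragment grouping by retention-time window and Pearson correlation,
    representative selection), screens features for differential abundance
    between root types with ArcSinH normalization, Student t tests,
    Benjamini-Hochberg false discovery rate control and fold-change
    classification, and screens genotype-by-root-type designs with per-feature
    two-way ANOVA. Includes targeted quantification utilities (external-standard
    calibration, compound-specific MS-to-UV signal conversion, knockout
    percent-reduction summaries, 2^-ddCt relative expression), statistics for
    larval choice assays and ordinal root-damage scores, cross-referencing of
    enriched metabolites against known behaviorally active compounds, and a
    synthetic-data generator that emulates the statistical structure of all
    pipeline inputs with emitted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
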