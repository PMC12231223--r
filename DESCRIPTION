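Package: gekkodiet
Title: Stomach-Content Diet Composition Analysis for Insectivorous Lizards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative dietary ecology from stomach-flushing
    surveys of lizards and other small insectivores. Estimates prey-item
    volumes with the prolate-spheroid approximation, builds per-category
    diet composition tables (frequency of occurrence, numeric abundance,
    volumetric contribution and the Index of Relative Importance), ranks
    prey categories, and compares diets between sex and age groups with
    rank-based statistics (Wilcoxon rank-sum with exact enumeration,
    Kendall's tau-b with tie correction, Pearson correlation and ordinary
    least squares for morphometrics). Includes an uncorrected pairwise
    p-distance module for COI barcode alignments used to confirm
    conspecificity of sampled individuals, a seeded synthetic-data
    generator that emulates the statistical structure of a field survey
    of the black-eyed bent-toed gecko (Cyrtodactylus nigriocularis), and
    report writers producing tidy, publication-style output files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
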