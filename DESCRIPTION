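Package: radioshift
Title: Cell-Type Composition Shifts in Irradiated Lung Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting radiation- and
    antifibrotic-treatment-responsive expression programs in bulk lung
    microarray data and attributing them to shifts in cellular
    composition. Implements per-chip percentile normalization,
    normalization to contemporaneous unirradiated controls, a robust
    low-intensity probe filter, Welch-t / fold-change gene-list
    selection, principal-component extraction of the dominant
    treatment-associated expression pattern, derivation of
    cell-type-distinguishing marker panels from expression atlases
    (fold-ratio plus Mann-Whitney screening with cross-panel
    uniqueness), and fold-enrichment / chi-squared scoring of marker
    panels in query gene lists. A synthetic-data generator emulates the
    study design (noisy mixtures of cell-type profiles with planted
    composition shifts, and atlases with planted markers) so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
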