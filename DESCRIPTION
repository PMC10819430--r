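Package: quenchbind
Title: Fluorescence Quenching Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of protein-ligand binding from fluorescence quenching
    titrations, built around the serum-albumin binding assays used for
    per- and polyfluoroalkyl substances (PFAS). Provides inner-filter
    correction and spectral feature extraction, Stern-Volmer quenching
    analysis with static/dynamic/mixed mechanism classification,
    double-logarithmic binding-constant and binding-site estimation,
    Van't Hoff thermodynamics with interaction-force classification,
    competitive site-marker displacement analysis, MM/GBSA
    energy-decomposition validation and descriptor correlation, and a
    forward simulator of titration experiments with known ground truth.
    All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
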