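Package: culmr
Title: Culm Biomechanics and Lodging-Resistance Analysis for Rice Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying lodging resistance of rice from
    internode-level field measurements and for the accompanying
    transcriptomic comparison of nitrogen managements. Implements the
    hollow-cylinder beam mechanics of the culm (section moment of area,
    elastic modulus from three-point bending, flexural rigidity, bending
    moment, lodging index, culm volume and dry-matter densities),
    split-plot analysis of variance with LSD letter groups and
    percent-change summaries for two-treatment trials, and a two-color
    microarray pipeline (probe filtering, MA transform, loess dye-bias
    normalization, per-feature replicate tests, fold-change differential
    calls, hypergeometric GO enrichment and qPCR concordance). Seeded
    generators produce synthetic field trials and 44k-style two-color
    arrays with known truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
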