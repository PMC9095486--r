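Package: rnamodms
Title: Mapping and Characterization of RNA Modifications by Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico workflow for discovering and characterizing
    post-transcriptional RNA modifications by LC-MS/MS, built around the
    analysis that identifies 2'-phosphouridine in the variable loop of
    archaeal tRNA. Provides elemental-composition arithmetic and
    monoisotopic mass/m-z prediction for modified oligonucleotides,
    in-silico ribonuclease digestion (RNase T1, RNase A, RNase I,
    nuclease P1) with 2'-sugar-state cleavage blocking, CID c/y-ion
    ladder prediction with peak matching and modification-site
    localization, bounded elemental-composition search for unknown mass
    shifts, XIC-based modification stoichiometry and dose-response
    summaries, phenotype-constrained phylogenetic profiling of ortholog
    presence/absence matrices, and fits for melting curves, nuclease
    decay and Michaelis-Menten kinetics. Seeded synthetic-data
    generators emulate every input so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    minpack.lm,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
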