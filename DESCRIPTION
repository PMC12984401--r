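Package: phoscoreg
Title: Phosphosite-Centric Co-Regulation Meta-Analysis of Phosphoproteomic Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assemble compendia of published phosphoproteomic datasets,
    retain confidently localized (class-1) phosphosites, classify per-dataset
    regulation from fold changes and p-values, rank a protein's sites by
    detection and differential-regulation frequency, quantify directional
    co-regulation between an anchor phosphosite and phosphosites of other
    proteins with one-sided Fisher's exact tests and reproducibility filters,
    measure within-protein phosphosite co-occurrence, and map peptide
    evidence onto protein sequences (coverage and in-silico tryptic
    digestion). Includes a seeded simulator that generates compendia with
    planted co-regulation structure so every analysis stage can be validated
    offline, and a command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
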