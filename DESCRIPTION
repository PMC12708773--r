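Package: xovscreen
Title: Consensus Fingerprint-Based Virtual Screening for Xanthine
    Oxidase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A ligand-based virtual screening pipeline for prioritising
    xanthine oxidase inhibitor candidates among annotated plant-extract
    metabolites.  Covers curation and deduplication of labelled compound
    libraries, MACCS and extended-connectivity fingerprint encoding with
    Tanimoto diversity profiling, stratified 70/15/15 splitting,
    grid-searched gradient-boosted tree classifiers under an
    overfit-spread constraint, applicability-domain filtering by
    molecular weight and nearest-neighbour similarity, five-model
    consensus voting with decoy-spiked validation, and negative-mode
    adduct m/z and ppm-error arithmetic for metabolite annotation
    tables.  Includes a seeded synthetic library generator with an
    implanted substructure-activity rule so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    xgboost,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
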