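Package: pubcorpus
Title: Standardize Publication HTML into BioC, Table and Abbreviation JSON
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts heterogeneously structured full-text publication HTML
    (with inline or linked tables) into three machine-readable outputs: BioC
    JSON with publication sections annotated against the Information Artifact
    Ontology (IAO) document-part branch, a structured table JSON with per-cell
    identifiers, and an abbreviations JSON relating short forms to their
    definitions. Section headers are classified by a cascade of lexical
    normalization matching, longest-common-subsequence fuzzy matching, and
    prediction from a weighted directed graph of section-header sequences.
    Driven by user-editable source configuration files describing each
    publisher's HTML dialect. Includes a deterministic synthetic-article
    generator with exact ground truth for end-to-end validation, and a
    longest-common-subsequence similarity module for comparing outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
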