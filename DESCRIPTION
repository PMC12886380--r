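Package: silascreen
Title: Suspect Screening of Silicon-Containing Synthetic Cannabinoid
    Metabolites in LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Suspect-screening workflow for identifying metabolites of the
    silicon-containing synthetic cannabinoid receptor agonists
    ADMB-3TMS-PrINACA and Cumyl-3TMS-PrINACA in liquid
    chromatography-high-resolution mass spectrometry (LC-HRMS) data.
    Provides exact monoisotopic mass and adduct arithmetic with silicon as
    a first-class element, a phase I/II biotransformation rule engine that
    enumerates candidate metabolites and auto-MS/MS inclusion lists, a
    diagnostic product-ion knowledge base with fragment-shift logic for
    biotransformation site localization, tolerance-based precursor and
    fragment matching with retention-time discrimination of isobars,
    mean-area-ratio (MAR) ranking of urinary biomarkers, and a seeded
    synthetic LC-HRMS run generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
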