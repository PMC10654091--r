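Package: vaxbiome
Title: Infant Microbiome, Antibiotic Exposure, and Vaccine Response Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline linking early-life microbiome and
    metabolome features and antibiotic exposure to infant vaccine response.
    Provides antibody-titer quality control and composite outcome
    construction, threshold-based low/normal responder classification,
    grouped double-FDR exposure testing built on a zero-inflated Poisson
    likelihood-ratio test, rarefaction and alpha/beta diversity, per-feature
    Mann-Whitney and Spearman association screens with per-stratum
    Benjamini-Hochberg correction, and KEGG-module over-representation
    analysis. A synthetic cohort generator with known ground truth makes
    every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
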