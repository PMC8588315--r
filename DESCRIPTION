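Package: soiltox
Title: Soil Ecotoxicology Analytics for Dose-Response Microbiome Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pot-experiment soil ecotoxicology studies in
    which a contaminant is applied at graded doses with and without an organic
    biostimulant and the soil microbiome and enzyme responses are followed over
    time. Implements culture-based community indices (the colony development
    index CD and the ecophysiological diversity index EP), the biostimulation
    impact factor (ratio of treated to baseline activity), Tukey HSD post-hoc
    homogeneous groups with compact-letter display, Pearson dose correlations,
    PCA of impact-factor matrices, rank-wise OTU profile aggregation with
    abundance and difference filters, shared-taxon sets, and a two-proportion
    G-test (Yates) / Fisher exact hybrid with continuity-corrected confidence
    intervals. A seeded synthetic-data generator emulates the full factorial
    design (dose x time x biostimulant) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
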