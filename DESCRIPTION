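Package: snpplate
Title: Endpoint-Fluorescence SNP Genotype Calling and Genotyping-Platform
    Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing two-channel endpoint-fluorescence SNP
    genotyping plates (TaqMan, KASP, rhAmp and similar chemistries): a
    documented allele caller anchored on the no-template-control (NTC)
    centroid, cluster-geometry quality metrics (separation angle,
    NTC-to-cluster distance, cluster compactness), platform comparison by
    one-way completely-randomized-design ANOVA with Fisher LSD letter
    groupings, cross-platform genotype concordance, and a per-reaction kit
    cost model.  A seeded synthetic plate generator reproduces the
    statistical structure of a 384-well multi-platform genotyping
    experiment with ground-truth labels, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
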