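Package: dielgem
Title: Build and Analyse Diel (Day-Night) Plant Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms a non-diel plant genome-scale metabolic model into a
    diel model covering a full 24-hour light/dark cycle: day and night phases
    are created by duplicating every compartment, metabolite and reaction, a
    storage-pool compartment lets metabolites accumulate in one phase and be
    consumed in the other, photon uptake is blocked at night, the day:night
    nitrate uptake proportion is pinned by a linear coupling constraint
    (default 3:2), and the phase biomass reactions are merged into a single
    total-biomass objective. Ships an SBML Level 3 FBC reader/writer, a flux
    balance analysis (FBA) solver with a parsimonious variant, quantum-yield
    and storage-pool flux reporting, and a differential flux analysis toolkit
    (artificial-centering hit-and-run flux sampling, rank-based day/night
    tests with Benjamini-Hochberg correction, hypergeometric pathway
    enrichment, and a PCA overlap metric). Works on generic and multi-tissue
    models and includes generators for small synthetic photoautotroph models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
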