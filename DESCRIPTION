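Package: pahfate
Title: PAH Removal Rates, Equilibrium Partitioning and Hydrocarbonoclastic
    Bacteria Screening in Short-Term Seawater Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative workflow for two-timepoint seawater bottle
    incubations spiked with polycyclic aromatic hydrocarbons (PAHs):
    dissolved-phase removal-rate estimation with benchmark-compound
    correction, an octanol-water (Kow) equilibrium partitioning mass balance
    that bounds how much apparent removal can be explained by sorption to
    microbial biomass and dissolved organic carbon, exact Mann-Whitney and
    t-test comparisons with signed fold changes, and a genus-level screen of
    16S ASV count tables for enrichment of hydrocarbonoclastic bacteria.
    Includes synthetic-data generators for both incubation concentration
    series and ASV tables so every pipeline stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
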