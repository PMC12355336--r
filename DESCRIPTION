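Package: farmcf
Title: Farm-Level Carbon Footprint Accounting and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes whole-farm greenhouse-gas carbon footprints under the
    GHG Protocol scopes from annual activity data and a user-supplied
    emission-factor registry: Scope 1 direct emissions (enteric fermentation,
    manure management, soil nitrous oxide, fuel combustion, refrigerant
    leakage, on-site waste and biogas) and soil carbon sinks, Scope 2
    purchased energy, and Scope 3 input manufacturing with straight-line
    capital amortization plus off-site waste and wastewater. Derives
    emission intensities (per turnover, per hectare, per employee), the
    share of animal husbandry (SoAH), and scope and flow decompositions,
    and benchmarks farm cohorts via Spearman rank correlations and
    SoAH-matched pairwise comparisons. Includes a synthetic farm-cohort
    generator and delimited-text readers and writers for the farm data form.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
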