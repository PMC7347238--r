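Package: repex
Title: Quantifying Tandem Repeat Instability from Fragment-Analysis Peak Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying CGG-repeat instability in cultured cells from
    capillary-electrophoresis fragment-analysis data. Reads genotyping peak
    tables, converts fragment sizes to repeat numbers, calls modal alleles and
    computes the Expansion Index (a windowed variant of the Somatic Instability
    Index), estimates expansion rates over time courses by linear regression,
    and analyzes small-pool PCR single-molecule allele distributions
    (exact/approximate rank-sum comparison, expanded-allele classification,
    Poisson limiting-dilution occupancy). A stochastic stepwise-expansion
    simulator with PCR-stutter trace rendering and limiting-dilution sampling
    provides ground-truth synthetic data for every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
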