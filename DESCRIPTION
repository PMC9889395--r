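Package: bloomcarbon
Title: Carbon Flow and Microbial Succession in Virally Infected Coccolithophore Blooms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mesocosm studies of Emiliania huxleyi bloom
    dynamics under viral infection. Fits recursive production-loss models that
    decompose transparent exopolymer particle (TEP), particulate inorganic
    carbon (PIC), particulate organic carbon (POC) and Coomassie-stainable
    particle (CSP) time series into per-cell production rates and a daily loss
    fraction; partitions the host population into infected and bystander cells
    to estimate an infected-cell production multiplier; quantifies community
    turnover and divergence from Bray-Curtis similarities; clusters taxon
    succession profiles; estimates growth, grazing and viral-lysis rates from
    paired dilution experiments; and converts ddPCR and cell-count assays into
    absolute abundances, biomass and carbon fluxes. A synthetic-data module
    generates complete in-silico mesocosm experiments with the statistical
    structure these analyses assume, so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    readr,
    jsonlite,
    generics,
    pracma,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
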