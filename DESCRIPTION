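Package: mycorootmap
Title: Mapping Fine-Root Biomass Carbon Colonized by Arbuscular and
    Ectomycorrhizal Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the workflow behind global
    maps of fine-root biomass carbon colonized by arbuscular (AM) and
    ectomycorrhizal (EcM) fungi. Builds spatial units from ecoregion, land
    cover and continent rasters; derives fine-root carbon stocks in the top
    30 cm from belowground biomass via coarse/fine root ratios and the
    asymptotic vertical root-distribution model; aggregates species-level
    root-colonization intensities to community-weighted plot and
    spatial-unit means; assembles colonized-root-carbon maps with
    ecoregion-by-continent gap-filling; and emits quality-index layers.
    Includes a synthetic-world generator with known ground truth so every
    stage is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
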