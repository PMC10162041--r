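Package: eDNAdesign
Title: Droplet Digital PCR Quantification, Multi-Method Occupancy
    Modelling and Survey Design for Lake eDNA Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing environmental DNA (eDNA) surveillance
    surveys of lakes sampled by droplet digital PCR (ddPCR). Converts
    droplet counts to target concentrations via Poisson partition
    statistics, applies rerun and two-of-three positivity rules,
    estimates the limit of quantification from dilution series, builds
    site-by-occasion-by-method detection histories, fits single-season
    multi-method occupancy models (large-scale occupancy, availability
    and method- or location-specific detection probability) by maximum
    likelihood with AIC model ranking, and searches for the minimum
    number of sampling sites and replicates that make whole-survey
    false negatives acceptably rare. A synthetic-data generator with
    known latent states supports validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ddpcr.R'
    'loq.R'
    'detection.R'
    'occupancy-likelihood.R'
    'occupancy-fit.R'
    'design.R'
    'synthetic.R'
    'io.R'
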