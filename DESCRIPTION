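Package: openfish
Title: Coupled Bioeconomic Size-Spectrum Modelling of Open-Access Fisheries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates commercially harvested fish biomass as size spectra
    driven by net primary production and temperature, coupled to prognostic
    open-access (Gordon-Schaefer) fishing effort. Biomass follows a
    McKendrick-von Foerster equation with allometric, temperature-dependent
    growth and mortality, stock-dependent recruitment, and a sigmoidal gear
    selectivity linking effort to a harvest spectrum. Includes a Monte Carlo
    parameter-calibration pipeline: prior sampling, transient
    catchability-ramp ensembles, constraint-based filtering on peak harvest,
    harvest size structure and harvest-to-biomass ratios, correlation ranking
    against observed per-ecosystem peak harvests, and Kolmogorov-Smirnov
    reporting of parameter-distribution shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'openfish-package.R'
    'mass_grid.R'
    'groups.R'
    'params.R'
    'ecology.R'
    'economics.R'
    'forcing.R'
    'model.R'
    'simulator.R'
    'calibration.R'
    'config.R'
    'plots.R'
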