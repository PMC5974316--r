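Package: smlvoc
Title: Photochemical VOC Emissions from the Sea-Surface Microlayer and
    Marine Secondary Organic Aerosol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global modelling toolkit for abiotic volatile organic compound
    (VOC) emissions produced by photochemistry at the surfactant-covered
    ocean surface. Maps sea-surface microlayer coverage from net primary
    production and wind-speed climatologies, computes the daily
    photochemical VOC emission potential and species-resolved emission
    fluxes on a 1-degree global grid, and couples the emissions to a
    marine-boundary-layer box model with OH oxidation and ten-bin
    volatility-basis-set gas/particle partitioning to estimate secondary
    organic aerosol formation. Includes a seeded generator of physically
    plausible synthetic climatologies so the full pipeline runs without
    external downloads, NetCDF readers and writers for gridded fields, and
    a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
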