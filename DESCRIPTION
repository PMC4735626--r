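Package: teleflux
Title: Teleconnection Phase-Composite Analysis of European Land Carbon Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link the joint winter phase of the North-Atlantic
    Oscillation (NAO) and East-Atlantic (EA) teleconnection patterns to
    anomalies of the European land CO2 sink (net biome productivity, NBP)
    and its photosynthesis/respiration components. Provides S4 containers
    for monthly and biweekly gridded fields, CF-style NetCDF input/output,
    conservative and bilinear regridding, pixel-wise deseasonalization and
    annual/seasonal anomaly integration, rotated principal-component
    circulation modes of 500-mb geopotential height, tercile-based NAO-EA
    phase classification and composite membership, composite significance
    testing (one-group and two-group ANOVA), EOF analysis of annual NBP
    anomaly fields with centres of action, and a seeded synthetic-data
    generator with a truth ledger for end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    ncdf4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
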