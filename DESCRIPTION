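Package: tllue
Title: Two-Leaf Light-Use-Efficiency Modelling of Sunlit and Shaded GPP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates daily gross primary production (GPP) of sunlit and
    shaded canopy fractions with a two-leaf light-use-efficiency model that
    includes temperature, vapour-pressure-deficit and CO2-concentration
    regulation scalars. Provides forcing preparation from flux-tower style
    daily records (VPD from specific humidity, shortwave-to-PAR conversion,
    solar geometry, site-year screening), canopy radiation partitioning into
    direct and diffuse streams and sunlit and shaded leaf area, calibration
    of the two maximum light-use efficiencies against observed GPP with a
    shuffled-complex-evolution optimizer, a small gridded product stage with
    8-day, monthly and annual GeoTIFF output and per-pixel trend analysis,
    and seeded synthetic flux-site and grid generators with known ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
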