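Package: CanopyYield
Title: Olive On-Year Yield Forecasting from Canopy Geometry and UAS Orthoimagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forecasts per-tree olive "on-year" yield from tree canopy
    geometry. Computes manual canopy volume from surveying-rod measurements
    (ellipsoid model), delineates individual tree crowns on RGB orthoimages
    by dual-threshold segmentation of the green band followed by connected
    component labelling, fits and applies linear yield forecast models
    (including the chained crown-area to canopy-volume to yield forecast),
    aggregates to orchard level, and renders per-tree thematic yield maps.
    Includes a synthetic orchard generator (grid layouts, truncated-normal
    tree populations, rendered orthoimages with crowns and shadows) so the
    whole pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, graphics, png, jsonlite
Suggests: testthat (>= 3.0.0), withr, EBImage, tiff, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
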