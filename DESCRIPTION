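Package: apisite
Title: Apiary Site Evaluation and Colony Stocking from Annotated Landscapes
Version: 0.1.0
Authors@R:
    person("Apisite", "Developers", email = "apisite@example.org", role = c("aut", "cre"))
Description: Estimates how many honey-bee colonies a candidate apiary location
    can support. A semantically annotated landscape (field polygons carrying
    nectar-productivity and pesticide-contamination coefficients, classified
    road polylines) is intersected with the colony flight circle; per-segment
    honey yields, road-crossing availability penalties and road-proximity
    losses are combined into a total honey estimate and a supportable colony
    count. Includes a GeoJSON-dialect reader/writer, a pure-R planar geometry
    kernel (circle-polygon clipping, road partition of the map, buffer-overlap
    areas), a seeded synthetic landscape generator, a layer renderer and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
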