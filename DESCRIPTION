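Package: landsec
Title: Landscape Ecological-Security Assessment, Hotspot Analysis and
    Ecological Zoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for landscape ecological-security
    assessment on categorical land-use rasters: DPSIR (Driving
    forces-Pressure-State-Impact-Response) composite indices on a 1-km
    assessment grid with AHP-derived weights, land-use transfer matrices
    and grassland degradation/restoration intensities, global Moran's I
    with permutation inference, Getis-Ord Gi* hotspot fields with
    seven-grade classification and an FDR-corrected scale-optimized
    variant, time-space overlay zoning into risk-warning and protection
    classes, and minimum-cumulative-resistance (MCR) cost-distance
    delineation of protection areas. Includes a seeded synthetic-landscape
    generator emulating an oilfield degradation scenario so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
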