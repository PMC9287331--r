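Package: aridipet
Title: FAO-56 Penman-Monteith Reference Evapotranspiration and Aridity Index Grids
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes FAO-56 Penman-Monteith reference evapotranspiration
    (ET0) and the aridity index (AI, precipitation over ET0) from monthly
    climatology inputs, both for single locations (weather-station records)
    and on georeferenced raster grids. Implements the full scalar chain of
    psychrometric primitives (atmospheric pressure, psychrometric constant,
    vapour pressures, slope of the saturation vapour pressure curve), the
    daily radiation budget (extraterrestrial, clear-sky, net shortwave and
    longwave radiation), the reference-crop combination equation with fixed
    bulk surface resistance, UNEP aridity classification and the x10000
    integer distribution encoding, a block-streaming raster engine over
    ESRI ASCII grids, station-versus-grid validation statistics, and
    deterministic synthetic climate fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
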