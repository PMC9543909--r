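Package: mesoflux
Title: Leaf Photosynthesis, Mesophyll Conductance and Airspace Diffusion Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Fits Farquhar-von Caemmerer-Berry (FvCB) CO2 response curves with
    mesophyll-conductance coupling and limitation-state partitioning, and
    extracts the CO2-saturated assimilation rate from the triose-phosphate-use
    state. Estimates mesophyll conductance from chlorophyll fluorescence by the
    variable-J method and the intercellular CO2 photocompensation point and day
    respiration by the Laisk intersection method. Computes three-dimensional
    mesophyll diffusion traits from segmented microCT leaf volumes: porosity,
    exposed mesophyll surface density, geodesic tortuosity, lateral path
    lengthening, vein fraction, thicknesses, stomatal density and the
    intercellular airspace conductance. Includes seeded generators for labeled
    leaf phantoms, simulated gas-exchange curves and monthly climate tables
    with known ground truth, plus study-level statistics: intrinsic water-use
    efficiency, climate seasonality coefficients of variation,
    Bonferroni-controlled correlation matrices and dehydration-response
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
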