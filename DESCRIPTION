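Package: tillerct
Title: Micro-CT and RGB Phenotyping of Rice Tillers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for bimodal micro-CT / RGB
    phenotyping of rice shoot architecture. Generates virtual multi-tiller
    plants with known geometry, simulates limited-angle X-ray projection
    stacks, reconstructs transverse slices by filtered back-projection,
    segments tiller cross-sections and extracts the tiller trait catalogue
    (counts, areas, diameters, wall thickness, inclination angles), computes
    side-view RGB traits (color, digital biomass, architecture, fractal
    dimension, histogram and co-occurrence texture), and fits growth curves
    with agreement metrics, tiller senescence, and stepwise yield models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    Rcpp,
    mgcv,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
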