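Package: fungalmorph
Title: Quantitative Macro-Morphology and Germination Kinetics of Filamentous Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the macro-morphology of filamentous fungi
    (Aspergillus niger and similar organisms) from particle images and to relate
    morphology to cultivation performance. Implements Otsu thresholding, particle
    extraction and the shape descriptors circularity, solidity and aspect ratio,
    combined into a dimensionless Morphology number; a laser-diffraction
    germination assay based on the volume-median diameter (Dv50) and the Sauter
    mean diameter (D[3,2]) of particle-size-distribution time series, yielding
    lag phase and germination time; and cultivation-performance metrics
    (biomass-dry-weight integral, specific productivity, maximal growth rate)
    with an exponential correlation fit between Morphology number and specific
    productivity. A synthetic-data module generates particle images with analytic
    ground truth, germinating-population size distributions and cultivation time
    courses so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
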