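Package: TopoSIMS
Title: Topography-Aware Compression, Correction and Multivariate
    Analysis of ToF-SIMS Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated interpretation of time-of-flight
    secondary ion mass spectrometry (ToF-SIMS) imaging data. Implements
    lossless threshold-based compression of raw time-of-flight cubes
    onto informative mass segments, physics-based correction of
    topography-induced peak shifts using a reference ion, quantitative
    reconstruction of the sample surface topography from the
    mass-spectral shifts alone, and uncentered principal component
    analysis for chemical mapping. Includes a forward simulator of
    reflectron ToF-SIMS imaging with known ground truth, an imzML
    interchange layer, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    jsonlite,
    xml2,
    tiff
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
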