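Package: octmorph
Title: Retinal Layer Segmentation and Morphometry for Developing Mouse OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for quantifying retinal layer morphometry in
    spectral-domain optical coherence tomography (OCT) volumes of the
    developing mouse eye. Implements the full analysis chain: numerical
    dispersion compensation of spectral fringes, background subtraction and
    depth roll-off correction, rigid B-scan registration, frame averaging,
    speckle-variance angiography with motion-robust frame removal,
    semi-automatic intensity/derivative boundary detection of the retinal
    layers with optic-nerve-head exclusion and polynomial artifact
    correction, and layer-thickness measurement in cylindrical and annular
    regions of interest. A synthetic layered-phantom generator with known
    ground truth (speckle, vasculature, optic nerve head, sensitivity
    roll-off) supports validation of every stage, and rank-based group
    statistics summarise thickness tables across developmental time points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
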