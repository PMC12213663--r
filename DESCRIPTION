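Package: cryoclem
Title: Multi-Scale Registration and Morphometry for Cryo-CLEM of Neuronal Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for correlating cryo-fluorescence and cryo-electron
    microscopy images of vitrified specimens using fiducial markers at
    multiple scales. Provides sub-pixel detection of fluorescent beads and
    electron-dense gold particles, chromatic channel-shift correction,
    landmark-based estimation of planar similarity and affine transforms
    with fiducial and leave-one-out target registration errors, robust
    (consensus-based) fitting, tomogram z-projection, image warping and
    multi-channel overlay rendering, and morphometric analysis of synapse
    annotations (cleft-width profiling, vesicle-state classification,
    identification criteria). A synthetic scene generator with full
    ground-truth manifests makes every stage testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
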