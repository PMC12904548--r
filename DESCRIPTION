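Package: mesodeskew
Title: Oblique-Compensation Acquisition and De-Skewing Reconstruction for
    Light-Sheet Imaging of Tilted Tissue Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mesoscale selective-plane illumination microscopy
    (mesoSPIM-style) of thin tissue slices mounted at an oblique angle
    between the illumination and detection axes. Implements the coupled
    x-z stage-scanning geometry that mechanically compensates shear during
    acquisition, the matching volume-reconstruction pipelines (rotation or
    shear plus scaling, via a trilinear affine resampler), synthetic bead
    and nuclei phantoms imaged through an anisotropic Gaussian point spread
    function, per-bead Gaussian-profile FWHM quantification with R-squared
    gating and anisotropy statistics, nuclei segmentation and size
    measurement in sample coordinates, and closed-form accounting of
    padding, tiling and reconstructed data-size overheads for both scan
    modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
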