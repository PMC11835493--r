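Package: dermastretch
Title: Stereo Digital Image Correlation for Mapping Skin Stretch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An optical measurement chain for mapping two-dimensional skin
    stretch at millimetre resolution from multi-camera images of ink speckle
    patterns. Provides a synthetic scene generator (speckle textures,
    analytic deformation fields with closed-form ground-truth strain, and a
    pinhole rendering model), subset-based digital image correlation with
    subpixel refinement, stereo checkerboard calibration and triangulation,
    per-triangle Green-Lagrange membrane strain on tracked surface meshes,
    and plane-projected stretch maps with gradient, percentile, profile and
    axial orientation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    minpack.lm,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'speckle.R'
    'deformation.R'
    'camera.R'
    'calibration.R'
    'render.R'
    'dic.R'
    'mesh.R'
    'strain.R'
    'maps.R'
    'io.R'
    'pipeline.R'
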