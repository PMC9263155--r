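Package: ThermoRecon
Title: Volumetric Necrosis Map Reconstruction from Rotated 2D MR Thermometry Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a 3D coagulation-necrosis map of a thermal-ablation zone
    from a sparse set of 2D MR thermometry slices uniformly rotated about the
    ablation applicator's main axis. Implements four reconstruction backends
    (angular temperature interpolation, incremental Bowyer-Watson Delaunay
    triangulation with convex-hull voxelization, slice-wise minimum-volume
    enclosing ellipses via Khachiyan's algorithm, and closed periodic cubic
    B-spline contours filled by Sunday's winding-number test), together with
    PRFS phase-to-temperature mapping, configurable critical-temperature
    thresholding policies, relative-growth outlier rejection, a synthetic
    bio-protein phantom simulator with heat-sink vessels, and a Dice-based
    evaluation suite. Volumetric I/O uses NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
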