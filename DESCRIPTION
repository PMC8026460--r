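Package: Pelvimetry3D
Title: Three-Dimensional CT Pelvimetry: Segmentation, Meshing and
    Landmark-Based Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for three-dimensional bony-pelvis
    morphometry from CT-like volumes. Provides seeded level-tracing
    segmentation of axial slices, isosurface extraction of the bone mask
    with volume-audited Laplacian smoothing, a fiducial-landmark schema
    with Slicer-compatible input/output, computation of 21 pelvimetric
    measures (inlet and outlet conjugates, diameters and pelvic angles),
    sex-stratified cohort statistics with a-priori power analysis, and a
    calibrated synthetic-phantom generator so that every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    pracma,
    EBImage,
    RNifti
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
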