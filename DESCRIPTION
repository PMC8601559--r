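Package: gradocc
Title: Dual-Axis Landscape Gradients and Single-Season Occupancy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies heterogeneous, human-dominated landscapes as
    continuous gradient surfaces and links them to species occurrence with
    single-season occupancy models.  Categorical land-cover rasters are
    decomposed into per-class binary indicators, smoothed with a Gaussian
    kernel to continuous class-fraction surfaces, and ordinated with a
    correlation-matrix principal components analysis; axes retained under
    the broken-stick rule yield a hard-to-soft (built to vegetated) and a
    brown-to-green (agricultural to natural) gradient surface.  A
    maximum-likelihood single-season occupancy engine with logit-linear
    occupancy and detection submodels supports AICc-based two-stage model
    selection over candidate sets, parametric-bootstrap goodness of fit,
    simulation, and prediction.  A seeded synthetic-landscape and
    synthetic-checklist generator exercises the complete pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
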