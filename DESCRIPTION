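Package: mbrt
Title: Orthovoltage X-Ray Minibeam Radiotherapy Dose Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale in-silico evaluation of orthovoltage X-ray minibeam
    radiation therapy (MBRT) for ocular targets. Provides a kilovoltage
    photon Monte Carlo dose engine for voxel phantoms (Woodcock delta
    tracking, Klein-Nishina Compton sampling, kerma approximation), a
    parametric model of divergent multi-slit brass collimators, a synthetic
    eye/head voxel phantom generator with region-of-interest labelling,
    CT-like raster ingestion, and the spatial-fractionation dose analysis
    pipeline: lateral profiles, peak/valley detection, FWHM and
    centre-to-centre spacing, peak-to-valley dose ratios, per-ROI dose
    summaries with prescription scaling, and batch-based per-voxel
    uncertainty estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
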