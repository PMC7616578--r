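Package: fetalt2star
Title: Quantitative T2* Fetal Body MRI Reconstruction at Low Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative T2* relaxometry of the fetal body from
    low-field multi-echo dynamic gradient-echo MRI. Provides motion quality
    control, Marchenko-Pastur PCA (MP-PCA) patch denoising, voxel-wise
    mono-exponential T2* fitting, rigid slice-to-volume registration with
    point-spread-function based super-resolution and a deformable refinement
    stage, propagation of the recovered transforms to quantitative T2* maps,
    organ-wise statistics with fit-failure exclusion, reconstruction
    equivalence checks, Dice overlap evaluation, and gestational-age growth
    curves. Includes a digital moving-fetus phantom and acquisition simulator
    so the whole pipeline can be exercised and validated without scan data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
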