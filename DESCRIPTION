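Package: lacycle
Title: Time-Varying Left-Atrium Analysis from ECG-Gated Cardiac CT
Version: 0.1.0
Authors@R: person("BioCardio", "Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for rhythm analysis of the left atrium
    from ECG-gated cardiac CT series. Provides NIfTI volume input/output
    with Hounsfield-unit clipping, min-max normalisation, isotropic
    resampling and mask-guided cropping; online affine augmentation
    (rotation, shear, scale); a residual 3D U-Net segmenter trained with a
    two-class soft Dice loss under a phase-stratified five-fold
    cross-validation scheme; volume-overlap and signed surface-distance
    evaluation; per-phase left-atrial volumetry with cyclic spline volume
    curves and the derived expansion index (LAEI), emptying fraction (LAEF)
    and antero-posterior (AP) diameter; a nu-parameterised one-class
    support vector machine that separates sinus rhythm from atrial
    fibrillation, with autoencoder and clustering baselines; and a 4D
    phantom generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
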