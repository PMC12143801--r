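# lacycle

Time-varying left-atrium analysis from ECG-gated cardiac CT.

## The problem

Atrial fibrillation (AF) remodels the left atrium (LA): contractility
drops, the chamber dilates, and stroke risk rises. ECG-gated CT
reconstructs one 3D volume at each of ten cardiac phases (0–90% of the
RR interval in 10% steps), so the LA volume can be tracked through the
whole cycle — but only if the LA is segmented in every phase, which is
prohibitively slow by hand. `lacycle` is an R toolkit for the full
pipeline, aimed at researchers in cardiac image analysis:

* **Imaging I/O and preprocessing** — NIfTI-1 read/write, HU clipping to
  \[-350, 800\], fixed-range min–max normalisation, 1 mm isotropic
  resampling, mask-guided cropping, SNR measurement.
* **Augmentation** — online affine augmentation (rotation ±0.2 rad,
  shear ±0.05, ±15% volume scaling), identical on image and mask.
* **Segmentation** — a residual 3D U-Net (depth 3, feature widths
  32–64–128–256–128–64–32, instance normalisation, PReLU, concatenating
  skips, sigmoid head) trained with the two-class soft Dice loss

  `DL = 1 − (Σ pₙrₙ + ε)/(Σ (pₙ+rₙ) + ε) − (Σ (1−pₙ)(1−rₙ) + ε)/(Σ (2−pₙ−rₙ) + ε)`

  under Adam and early stopping, with a phase-stratified 5-fold scheme
  (fold *k* tests on phases {(k−1)·10%, (k−1)·10%+50%}) and a 36/12/12
  patient split. The network and its backpropagation are implemented in
  the package (im2col + BLAS; no external DL framework) and verified by
  finite differences.
* **Evaluation** — volume-level Dice / precision / recall and signed
  node-to-node surface distances with histograms.
* **Volumetry** — per-phase LA volumes, periodic cubic-spline volume
  curves, and the rhythm features
  LAEI = (LAVmax−LAVmin)/LAVmin·100,
  LAEF = (LAVmax−LAVmin)/LAVmax·100, and the AP diameter (set diameter
  of the border of the largest-area axial slice at maximal volume).
* **Rhythm classification** — a ν-one-class SVM (SMO dual solver,
  linear/poly/RBF/sigmoid kernels, γ = 1/(n·var X)) treating sinus
  rhythm as the outlier class, tuned by grid search and evaluated under
  a deterministic group 5-fold; plus autoencoder and clustering
  baselines (DBSCAN, GMM, mean shift).
* **Phantoms** — a 4D lobed-ellipsoid phantom generator (0.45 mm
  in-plane, 1 mm slices, SNR 0.79, SR/AF volume programs) and a
  class-conditional Gaussian rhythm-feature simulator, so everything is
  testable without patient data.

## Worked example

```r
library(lacycle)

# 10-phase synthetic sinus-rhythm series at reduced grid scale
cfg <- phantom_config(shape = c(64L, 64L, 48L), spacing = c(1, 1, 1),
                      atrium = c(10, 11, 12), appendage = c(4, 4, 5),
                      volume_program = sr_volume_program(4, 8), seed = 1)
series <- make_phase_series(cfg)
masks <- lapply(series, `[[`, "mask")
f <- volumetric_features(masks)
cat(sprintf("LAEI %.1f%%  LAEF %.1f%%  AP %.1f mm\n", f$laei, f$laef, f$ap))
#> LAEI 102.3%  LAEF 50.6%  AP 26.3 mm
round(f$curve$lav, 2)
#>  [1] 4.39 5.38 6.56 7.62 8.02 7.62 6.56 5.38 4.39 3.96
```

The programmed cycle runs 4 → 8 mL peaking at the 40% phase, so the
true expansion index is 100% and the true emptying fraction 50%; the
recovered 102.3% / 50.6% reflect voxelisation error only, and the ten
interpolated volumes trace the raised-cosine program. The phantom's
noise is calibrated to the acquisition SNR:

```r
rois <- phantom_rois(cfg)
compute_snr(series[[1]]$vol, rois$signal, rois$noise)
#> measured SNR 0.85   (target 0.79)
```

Rhythm classification on a simulated cohort (22 AF, 11 SR):

```r
tab <- make_rhythm_table(rhythm_sim_config(seed = 1))
res <- evaluate_ocsvm(as.matrix(tab[, c("laei", "laef", "ap")]),
                      tab$label, ids = tab$patient_id)
res$report
#> <classification_report> tp 11 fp 1 tn 21 fn 0 |
#>   sens 100.0% spec 95.5% acc 97.0% b-acc 97.7%
```

Sensitivity counts correctly flagged SR patients (the outlier class),
specificity correctly retained AF patients.

A YAML-configured pipeline (`run_pipeline()` /
`inst/scripts/la-cycle`) chains phantom generation, preprocessing,
feature extraction and classification, writing NIfTI/CSV/JSON artifacts
and a checksummed run manifest.

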