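# siribruise

Detection of subsurface bruises in fruit with **structured-illumination
reflectance imaging (SIRI)**, as an end-to-end, fully reproducible R
pipeline: synthetic phantom acquisition, three-phase demodulation,
contrast-index frequency optimization, GLCM texture features, random-frog
feature selection and LS-SVM / PLS-DA / KNN classification.

## The problem and who this is for

Fresh bruises under the skin of thin-skinned fruit (pears, apples, peaches)
are nearly invisible under uniform illumination: the planar reflectance of
the tissue barely changes. SIRI projects sinusoidal fringe patterns on the
fruit and demodulates the reflected images. The modulated (AC) component
interrogates a shallow, frequency-dependent tissue depth where bruises
scatter and absorb differently, so bruises that are invisible in ordinary
images appear as dark patches. This package is for researchers in
postharvest quality assessment and biological image analysis who want a
tested, scriptable implementation of the full SIRI bruise-detection
analysis chain — and, because public SIRI bruise datasets are scarce, a
ground-truthed synthetic scene generator to develop and validate against.

## The method

Three pattern images are acquired at phase offsets −2π/3, 0, +2π/3:

    I_n(x, y) = I_DC(x, y) + I_AC(x, y) · cos(2π f x + φ_n)

Three-phase demodulation (TPD) recovers both components pixel-by-pixel:

    I_DC = (I₁ + I₂ + I₃) / 3
    I_AC = (√2 / 3) · √[(I₁−I₂)² + (I₁−I₃)² + (I₂−I₃)²]

and the ratio image `RT = I_AC / I_DC` cancels surface reflectance and
curvature vignetting, flattening the background and boosting bruise
contrast. The operating spatial frequency is chosen by sweeping candidate
frequencies and scoring each with the **contrast index**

    CI = [N_x (x̄ − z̄)² + N_y (ȳ − z̄)²] / Σᵢ (zᵢ − z̄)²

— the between-class share of the pixel-intensity variance for the Otsu
bruise/sound partition of the masked RT image (x = bruised, y = sound,
z = whole fruit; CI ∈ [0, 1]). Classification uses 56 Haralick texture
features (14 statistics × 4 directions, distance 1) extracted from the
masked AC or RT image, optionally reduced to the 10 features most often
selected by repeated random-frog runs, and binary classifiers (LS-SVM with
RBF kernel solved as one linear KKT system, PLS-DA with LOO-chosen latent
variables, KNN) evaluated over 30 stratified 7:3 train/test splits
reporting TP/TN/ACC with standard errors.

## Worked example

```r
library(siribruise)

# a moderate-bruise phantom, imaged at 150 cycles/m with sensor noise
ph <- make_phantom("S2", seed = 3)
tr <- render_triplet(ph, illumination_spec(150), noise_spec(1, TRUE, seed = 9))
dm <- demodulate(tr, sigma = 2)
dm
#> SIRI demodulation (256x256 px, f = 150 cycles/m, AC filter sigma = 2 px)
#>   DC range [0.00, 119.33]; AC range [0.29, 89.32]; RT range [0.000, 85.698]
# (the extreme RT values sit on near-zero-DC background pixels, which the
#  fruit mask removes before any statistic is computed)

thr <- min(dm$dc) + 0.1 * diff(range(dm$dc))
fm  <- erode_mask(fruit_mask_from_dc(dm$dc, thr), 6)
seg <- split_bruise_sound(dm$rt, fm)
seg
#> SIRI segmentation: fruit 23173 px = bruise 1481 px + sound 21692 px
#>   (threshold 0.5811, separability 0.927)
round(contrast_index(dm$rt, seg)$ci, 4)
#> [1] 0.9274

# frequency sweep on noiseless (8-bit) renders: CI rises to 150 and falls
sw <- frequency_sweep(frequencies = seq(50, 500, 50), replicates = 3,
                      noise = noise_spec(0, quantize = TRUE), seed = 2)
sw
#> Contrast-index frequency sweep (RT images):
#>       50   100   150   200   250   300   350   400   450   500
#> S1 0.753 0.841 0.854 0.846 0.824 0.789 0.736 0.665 0.576 0.525
#> S2 0.894 0.925 0.929 0.926 0.919 0.907 0.888 0.858 0.814 0.749
#> S3 0.931 0.946 0.947 0.946 0.943 0.937 0.928 0.914 0.891 0.855
#> Selected operating frequency: 150 cycles/m
```

The segmentation recovers the planted bruise disk (Dice ≈ 0.99 here), the
contrast index quantifies its visibility, and the sweep selects
150 cycles/m — the frequency at which the phantom's bruise contrast was
designed to peak — under the "mild-first" rule that prioritizes the
hardest-to-detect mild bruises.

A full study (simulate → demodulate → segment → sweep → features → select →
evaluate) runs from one configuration object and one master seed:

```r
res <- run_pipeline(siri_config(seed = 1, n_per_class = 30), "out/")
head(res$report)
```

Every stage artifact (pattern PNGs + manifest, float-TIFF demodulation
products, masks, CI table, feature and tally CSVs, evaluation CSV) is
persisted under `out/` with a provenance log; a rerun with the same config
reproduces every CSV bit-identically. A thin command-line wrapper is at
`inst/scripts/siri-pipeline.R`.

## Scope

The package implements the analysis chain on synthetic phantoms whose
statistical structure (vignetted elliptical fruit, frequency-dependent
bruise contrast with a rise-then-fall profile, tissue texture, 8-bit
sensor) emulates desk-scale SIRI acquisitions. Hardware control, RGB
imaging and radiative-transfer light-propagation modelling are out of
scope; see the methods vignette (`vignettes/siri-methods.Rmd`) for the
model, its assumptions and its limitations.
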