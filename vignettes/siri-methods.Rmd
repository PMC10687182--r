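---
title: "Structured-illumination bruise detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured-illumination bruise detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(siribruise)
```

This vignette is the package's account of the science it implements: the
acquisition and demodulation model, the synthetic scene that stands in for
real fruit, the statistics and learning components, the numerical choices,
and what the package's tests do and do not establish about real data.

## 1. Acquisition model and three-phase demodulation

A structured-illumination reflectance imaging (SIRI) system projects a
sinusoidal fringe pattern on the sample and photographs the diffuse
reflection. With fringes along the image columns only, the n-th pattern
image is

$$I_n(x, y) = I_{DC}(x, y) + I_{AC}(x, y)\,\cos(2\pi f x + \varphi_n),
\qquad \varphi_n \in \{-2\pi/3,\, 0,\, +2\pi/3\},$$

where $x$ is the column coordinate in metres and $f$ the spatial frequency
in cycles·m⁻¹. $I_{DC}$ is the planar component — what a uniformly lit
photograph would record — and $I_{AC}$ is the amplitude of the modulated
component, whose depth of interrogation shrinks as $f$ grows; that depth
selectivity is what makes shallow subsurface bruises visible.

Three-phase demodulation (`tpd_demodulate()`) inverts the three equations
per pixel:

$$I_{DC} = \tfrac13 (I_1 + I_2 + I_3), \qquad
I_{AC} = \tfrac{\sqrt 2}{3}\sqrt{(I_1 - I_2)^2 + (I_1 - I_3)^2 + (I_2 - I_3)^2}.$$

The recovery is exact for ideal sinusoids at *any* carrier phase (the test
suite sweeps the carrier over $[0, 2\pi)$ and checks both components to
1e-6), and the pairwise differences cancel any additive offset common to
the three exposures. The ratio image $RT = I_{AC}/I_{DC}$ cancels
multiplicative structure shared by both components — surface albedo,
curvature vignetting — which is why RT images have flat backgrounds and the
strongest bruise contrast. Division is guarded: where $I_{DC} \le
\varepsilon$ (default $10^{-9}$), RT is set to 0; such pixels are
off-fruit background that the mask removes anyway.

The AC image is denoised with a separable Gaussian low-pass filter
(`gaussian_lowpass()`, default $\sigma = 2$ px, kernel truncated at
$4\sigma$ and renormalized, symmetric boundary reflection) *before* the
ratio is formed, so the division does not amplify AC noise. Neither the
filter width nor the order is dictated by the physics; both are arguments
of `demodulate()`.

One consequence of filtering before masking is an artefactual dark ring in
RT at the fruit rim: the filter mixes background zeros into AC where DC is
still large. All downstream consumers therefore erode the fruit mask by
$\lceil 3\sigma \rceil$ pixels (`erode_mask()`) before segmenting or
extracting features. Without this margin the rim ring, not the bruise,
dominates the Otsu split of mildly bruised fruit.

## 2. The synthetic scene

No public image sets exist for this task, so `make_phantom()` +
`render_triplet()` generate ground-truthed acquisitions whose statistical
structure emulates desk-scale SIRI imaging of a pear-like fruit:

* **Geometry.** A 256×256 image at 0.5 mm/px (configurable). An elliptical
  fruit (axes ≈ 0.40·width, 0.34·height) with per-sample jitter of centre,
  axes, reflectance level and vignette depth. At this pitch the highest
  swept frequency, 500 cycles·m⁻¹, is 0.25 cycles/px — four pixels per
  fringe, comfortably below Nyquist.
* **Reflectance.** Base diffuse reflectance 0.85 with a radial cosine
  falloff of depth 0.35 toward the rim (the darker-edge vignetting that
  curvature produces in DC images), plus a smooth multiplicative texture
  field (relative sd 0.05) emulating albedo mottle. Both cancel in RT.
* **Modulation.** The AC amplitude carries a modulation transfer envelope
  $M(f) = e^{-f/600}$ (cycles·m⁻¹), reproducing the darkening of AC and RT
  images at high fringe density, times a smooth tissue-texture field
  (relative sd 0.025, correlation length 3 px) that *survives* in RT — this
  is the within-tissue heterogeneity that gives RT images texture and the
  contrast index a finite variance floor.
* **Bruise.** A disk strictly inside the fruit that attenuates only the
  modulated component by the rise-then-fall profile
  $c(f) = \delta\,(f/f_{peak})\,e^{1 - f/f_{peak}}$ with $f_{peak} = 150$
  cycles·m⁻¹. Severity grades set the attenuation depth and radius:
  S1 (mild) $\delta = 0.35$, r = 18 px; S2 $\delta = 0.55$, r = 22 px;
  S3 (severe) $\delta = 0.75$, r = 26 px; S0 (sound) has no bruise. The
  one-parameter profile is the simplest curve with the observed
  rise-then-fall detectability; its peak is placed at the frequency the
  study design singles out.
* **Sensor.** Additive Gaussian read noise (default sd 1 count) and 8-bit
  clipping/rounding. "Noiseless" study conditions keep the quantization:
  it is part of the acquisition, and its frequency-independent noise floor
  is physically what limits contrast at strong attenuation.

Everything is seeded; the same seed reproduces scenes, renders and written
PNG files bit-identically.

**Calibrating the texture amplitude.** The texture sd (0.025) is the one
generator parameter that is *constrained* rather than free. The contrast
index of a bruised fruit behaves like
$CI(f) \approx \max\{B(f),\, 0.64\,V\} / (B(f) + V)$, where
$B(f) \propto p(1-p)\,c(f)^2$ is the bruise's between-class variance
($p$ = bruise area fraction), $V$ the within-tissue variance, and
$0.64\,V$ the best-split variance share that Otsu extracts from an
unbruised, roughly Gaussian texture field. Once $B$ falls below that
floor the measured CI curve stops tracking $c(f)$ and climbs back toward
the floor — so for the design requirement that every degree's CI row be
unimodal over the 50–500 sweep with its interior maximum at 150, the
*mild* bruise must remain the dominant split at the far end of the sweep:
$B_{S1}(500) > 0.65\,V$, i.e. $\sigma_{tex} \lesssim 0.11\,\delta_{S1}
\approx 0.038$. The default 0.025 keeps a ~1.5× margin (the AC filter
further shrinks the effective texture variance). This is the package's own
statement of the regime it emulates: mild bruises are detectable but
hardest, exactly the regime in which frequency optimization matters.

## 3. Segmentation and the contrast index

The fruit mask comes from thresholding the DC image (`fruit_mask_from_dc()`,
default threshold 10 % of the DC dynamic range — one manual value reused
for all samples, as a stable imaging geometry permits), followed by a
morphological closing (disk radius 3 px), hole filling and retention of
the largest 4-connected component. The bruise/sound partition applies
Otsu's method to the RT values inside the (eroded) mask, labelling the
darker class as bruised; polarity is an argument for other defect types.
`otsu_threshold()` scores each of the 255 interior bin edges of a 256-bin
histogram with *exact* per-bin value sums, so it coincides with an
exhaustive search and ties break deterministically to the lowest
threshold. Sound fruit still yields a split — Otsu always does — so the
partition carries a separability statistic and a warning below a
configurable floor.

The contrast index of a partition is the between-class share of the total
pixel-intensity variance,

$$CI = \frac{N_x(\bar x - \bar z)^2 + N_y(\bar y - \bar z)^2}
            {\sum_{i=1}^{N_z} (z_i - \bar z)^2} \in [0, 1],$$

invariant to affine intensity rescaling. The frequency sweep
(`frequency_sweep()`) renders each replicate phantom at every candidate
frequency (three replicates per degree by default, mirroring a small
calibration set of physical samples re-imaged at each frequency), computes
CI on RT (RT rather than AC because mild-bruise segmentation is only
reliable after ratio enhancement), and averages per cell.
`select_frequency()` implements the **mild-first** rule: argmax of the
mildest degree's CI, ties broken by the next degree and then by the lower
frequency — mild bruises are the hardest to detect, so the frequency is
chosen for them.

## 4. Texture features

`feature_vector()` produces exactly 56 features: the masked image is
min–max quantized to 32 gray levels (per-image normalization, appropriate
for floating-point RT images whose absolute scale varies with frequency;
level count configurable), a symmetric, unit-normalized co-occurrence
matrix is accumulated at distance 1 for each of the four directions 0°,
45°, 90°, 135° (both pixels of a pair must lie in the mask), and
Haralick's 14 statistics are computed per direction in a fixed, named
order. Entropies use base-2 logarithms with $0\log 0 = 0$. Degenerate
inputs have defined fallbacks — correlation and the maximal correlation
coefficient are 0 when a marginal variance vanishes, the information
measures are 0 when the relevant entropies vanish — so vectors are always
finite, even for constant regions. Symmetric normalization is required for
the correlation-type statistics to be well defined; the fixed naming keeps
selection tallies comparable across runs. Features are computed on the
full masked fruit (not a bruise-centred crop): at deployment the bruise
location is unknown.

## 5. Random-frog feature selection

`random_frog()` performs a reversible-jump-MCMC-like search over feature
subsets: from a current subset of size $Q$, a candidate of size
$Q^\ast = \max(1, \mathrm{round}(N(Q, \theta Q)))$ is proposed by adding or
removing uniformly chosen features (a size-preserving proposal swaps one
member for one non-member — without it, chains cannot mix between
exchangeable features), scored by stratified cross-validated PLS-DA
misclassification (`plsda_cv_error()`, error taken at the best LV count up
to min(10, subset size)), accepted if better, and otherwise accepted with
probability $\eta \cdot err_{cur}/err_{cand}$ capped at 1. A feature's
selection probability is the fraction of iterations whose retained subset
contains it.

Two numerical choices matter in practice. First, one CV fold assignment is
drawn per run and reused for every candidate: re-randomizing folds per
candidate makes acceptance fold-luck-driven and the chain drifts into
bloated subsets whose members are indistinguishable. Second, scores are
memoized by subset, which the fixed folds make exact. Defaults
($Q_0 = 10$, $\theta = 0.3$, $\eta = 0.1$, 5 folds, 1000 iterations) are
in the range of the original random-frog literature; all are arguments.

`tally_over_partitions()` repeats the search on the training side of 30
stratified 7:3 splits, counts how often each feature enters a run's top
ten, and returns the ten features with the highest counts (ties by mean
selection probability, then feature order). Redundancy is the selector's
intrinsic limit: once a subset separates the classes, additional
informative features are interchangeable with noise for a misclassification
scorer, so recovery is assessed on data where classes overlap enough that
every informative feature has marginal value. The planted-feature tests
use a lean initial subset ($Q_0 = 5$) for the same reason — small subsets
are the regime where dropping an informative feature is penalized.

## 6. Classifiers and evaluation

* **LS-SVM** (`lssvm()`): RBF kernel $K_{ij} = e^{-\|x_i - x_j\|^2/\sigma_k^2}$;
  training solves the $(n{+}1)\times(n{+}1)$ KKT system
  $[[0, \mathbf 1^\top], [\mathbf 1, K + I/\gamma]]\,[b; \alpha] = [0; y]$,
  $y_i \in \{-1, +1\}$. Every fit checks its KKT residual (< 1e-8).
  Hyperparameters come from 10-fold CV over a 7×7 logarithmic grid spanning
  $\gamma \in 10^{-1..4}$, $\sigma_k \in 10^{-1..2}$.
* **PLS-DA** (`plsda()`): PLS1 (NIPALS) on a 0/1 coding, threshold 0.5,
  latent variables chosen by leave-one-out CV with ties to fewer
  components. At full rank the fit equals multiple linear regression
  (tested to 1e-8).
* **KNN** (`knn_classify()`): Euclidean majority vote, odd K only (no vote
  ties), distance ties to the smaller training index, K tuned by 10-fold
  CV over 1, 3, …, 15.

`evaluate()` runs the repeated-split protocol: positives are the bruised
samples of the requested scope (one degree, or all three), negatives the
sound samples; each of 30 repetitions draws a stratified 7:3 split,
z-scores features on the training fold (applied to the test fold —
Haralick features mix scales, and distance-based models need
commensurability), optionally restricts to a selected 10-feature subset,
tunes, fits, and scores TP/TN/ACC. Reported are means and *standard
errors* over repetitions. The table is canonically sorted by sample id
before any seeded draw, so results are invariant to row order. A
degenerate split (single-class fold) is resampled with a derived seed and
a logged notice.

## 7. Problem sizes and reproducibility

The package's own studies are scaled for a desk machine: 30 samples per
class (the emulated protocol used 100), 256×256 images, 30 evaluation
splits, and selection chains of a few hundred iterations — sizes at which
the full pipeline runs in minutes on one CPU while leaving every
statistical property measurable. Every stage seed derives deterministically
from one master seed; `run_pipeline()` persists all artifacts plus a
provenance log and reproduces its CSVs bit-identically, with per-stage
caching keyed by a hash of the relevant config slice.

## 8. What the synthetic studies do and do not show

Passing tests establish that the implementation is faithful (demodulation
is exact, statistics equal their oracles, the pipeline recovers planted
structure: the designed frequency optimum, the bruise masks, the
informative features, near-perfect classification at the designed effect
sizes, and the RT-over-AC advantage when reflectance nuisance is present
and bruise contrast is weak). They do not certify performance on real
fruit: the phantom has no specular highlights, no stem/calyx concavities,
no shape irregularity beyond an ellipse, Gaussian-ish texture rather than
real tissue microstructure, a single circular bruise, and a
diffusion-free, single-parameter frequency response. Absolute CI values
and accuracies on real acquisitions will differ; the package's claims are
about the *methods*, their contracts and their relative behaviour.

## 9. Known limitations

* The contrast index saturates near 1 when within-tissue variance is very
  small; it is a ranking statistic for frequency selection, not a
  calibrated effect size.
* Otsu segmentation assumes one darker bruise class; multiple defects of
  mixed polarity need a different splitter.
* The LS-SVM solves a dense linear system — fine for hundreds of samples,
  cubic beyond that.
* PLS-DA here is binary (PLS1); multi-class grading of bruise severity is
  intentionally out of scope.
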