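---
title: "Multispectral texture classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral texture classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshisto)
```

## The problem

Colorectal biopsy slides stained with H&E show tissue classes that differ
mainly in glandular *texture*: normal mucosa shows round or tubular glands
in a regular lattice, hyperplastic polyps (HP) show elongated serrated
glands, tubular adenomas with low-grade dysplasia (TA_LG) show crowded
distorted tubes, and carcinoma (CA) shows disordered, fragmented
architecture. When each tissue field is imaged as a multispectral cube —
here 13 visual-spectrum (VS, 470–710 nm) and 26 infrared (IRS,
1150–1650 nm) bands, 20 nm apart — every band is a greyscale texture image
of the same scene under a different wavelength, and the classification
question becomes: how much does the spectral dimension add to the spatial
texture?

`mshisto` implements the full analysis stack for this question: per-band
texture descriptors, band selection, feature reduction, a stacked ensemble
classifier, sub-image label aggregation and, critically, a *patient-level*
cross-validation protocol.

## Texture descriptors

All six descriptors operate per band and concatenate their per-band blocks
in band order, so the feature length is always
`band_block_size * n_bands`:

| descriptor  | per-band block | 39-band length |
|-------------|---------------:|---------------:|
| GLCM        | 20             | 780            |
| histogram   | 11             | 429            |
| perception  | 5              | 195            |
| riLBP       | 4116           | 160524         |
| riLPQ       | 256            | 9984           |
| BSIF        | 1024           | 39936          |

**GLCM (Haralick).** Each band is quantized to 32 grey levels by per-band
min–max scaling (the quantization is a package choice; `glcm_levels` is a
parameter). Symmetric co-occurrence matrices are tabulated at displacements
1–5 pixels and angles 0/45/90/135°; the four angle matrices of each
displacement are averaged (making the statistics exactly invariant to
90° rotations) and normalized, and energy, contrast, homogeneity (the
`1/(1+|i-j|)` form) and correlation are read off. A constant band is given
energy 1, contrast 0, homogeneity 1 and correlation 1 by convention, so
degenerate tiles never produce NaNs.

**Histogram.** Mean, population variance, skewness, *non-excess* kurtosis,
and the raw (unstandardized) central moments of orders 5–11. Zero-variance
bands have skewness and kurtosis 0 by convention.

**Perception (Tamura).** Coarseness from the classic best-window averaging
pyramid (windows up to `2^tamura_kmax`, default 32 px, so bands must be at
least 32 px square); contrast `sd / kurtosis^(1/4)`; directionality as the
sharpness of the 16-bin gradient-orientation histogram, normalized so 1 is
a single dominant orientation and 0 is isotropic; line-likeness as the
mean direction co-occurrence `cos` at distance 4 px along the local edge
direction; roughness = coarseness + contrast. The five names fix the
family, not one canonical formula; the variants used here are stated
because published Tamura implementations differ in exactly these details.

**riLBP.** Circular local binary patterns in the (P, R) = (16, 2)
configuration with bilinear neighbour interpolation. The comparison is
`neighbour >= centre` so that flat regions give the stable all-ones code
(the interpolation is written in an anchored form that keeps constant
neighbourhoods exact in floating point). Codes are mapped to
rotation-invariant classes by taking the minimum over all 16 circular bit
rotations; the number of classes equals the number of binary necklaces of
length 16, which is 4116 — this is why the per-band histogram has 4116
bins, and the package verifies the count by brute-force enumeration of all
2^16 codes.

**riLPQ.** Short-time Fourier phase in a 15-px uniform window at the four
lowest non-zero frequencies; real/imaginary signs give an 8-bit code and a
256-bin histogram. Rotation invariance comes from estimating a per-pixel
characteristic orientation on a 36-direction grid and reading the code in
the rotated frame. One deliberate variant: the published orientation
estimate weights the directional resultant by the *sign* of the imaginary
STFT part. Because sign patterns are arc-like, that estimate falls exactly
on quantization-boundary ties at a large fraction of pixels, and
floating-point noise then picks the frame — under a 90° rotation about 40%
of codes changed. This package weights the resultant by the imaginary part
itself; the estimate is continuous, tie-free, and 90° rotations reproduce
the histogram exactly.

**BSIF.** Ten 7×7 linear filters, responses thresholded at zero into a
10-bit code (1024 bins). The built-in bank is learned once,
deterministically (fixed internal seed): patches are sampled from synthetic
1/f-spectrum noise images, patch means removed, PCA-whitened to 10
dimensions and rotated to independence by symmetric fixed-point ICA (tanh
nonlinearity). It is a *synthetic* stand-in for banks learned on natural
photographs — all length and code contracts are bank-independent, and an
external 7×7×10 bank can be supplied via `bsif_filter_bank`. The zero
threshold carries a tiny relative guard (`1e-9` of the response scale) so
that zero-mean filters on flat regions never flip bits through rounding.

Histograms are stored unnormalized (bin sums equal the number of coded
pixels); classifiers standardize features with training statistics, which
makes the normalization question moot downstream.

## Band selection by linear prediction

Bands are compared through 64×64 patches cut from the centre of every
band of every sample, pooled into one vector per band. Selection is
greedy: starting from an initial pair, the band whose pooled pixels are
*worst* predicted as an affine combination `a0 + sum aj Bj` of the
already-selected bands (least squares via QR; the normal-equations form
`(Y'Y)^{-1} Y'y` is the contract, a rank-deficient basis falls back to a
1e-8 ridge with a warning) is added until `k` bands are chosen. The greedy
order is deterministic, ties break to the lowest band index, and a
`k`-selection is always a prefix of a `k+1`-selection.

The initial pair is the middle VS band and the middle IRS band (lower
middle for even counts; with 13 + 26 bands that is bands 7 and 26,
1-based). Single-spectrum data falls back to the exhaustive
most-dissimilar pair.

Two open points were settled as follows:

* **LP error norm.** The error is the Euclidean norm over the pooled patch
  pixels of all samples (pooling, not per-sample aggregation).
* **Whitening.** `fit_whitening()` implements PCA whitening
  (`lambda^{-1/2} U'`) of the *band variables*, with pooled pixels as
  observations and an `epsilon` relative variance floor; whitened
  covariance is the identity on the fitting data. `select_bands()` exposes
  whitening as an option but defaults to `whiten = FALSE`: a signal
  whitening fitted on the very data used for selection equalizes all
  pairwise band correlations by construction, which reduces the LP
  dissimilarity criterion to tie-breaking. (Inside `select_bands` the
  symmetric, ZCA-form completion of the same eigendecomposition is used so
  that whitened variables stay attached to band indices.) The adjacent-band
  correlation screen reports the VS/IRS junction pair as cross-spectrum and
  never flags it: its low correlation reflects the change of light
  spectrum, not a bad band.

## Feature reduction

Global PCA (`fit_global_pca`, mean-centred, explained-variance ratios
exposed) is the default reduction, applied per descriptor in the ensemble
path and after concatenation in the concatenated path. The number of
components is nowhere canonical; the default is 64 per descriptor, capped
at `min(n - 1, d)` at fit time.

Feature selection via concave minimization (FSV) is provided for the
pairwise-vs-global comparison: minimize mean margin slack plus
`lambda` times a concave exponential surrogate (`1 - exp(-alpha |w|)`,
`alpha = 5`) of the weight zero-norm, by successive linear programs (at
most 50, convergence tolerance 1e-6 on `w`; `lambda = 0` degenerates to a
single plain separation LP). The LPs are solved by a small two-phase dense
tableau simplex with Bland's rule built into the package; the programs
involved are tiny, so robustness was preferred over speed. Pairwise
reducers (`fit_pairwise`) hold one map per unordered class pair, fitted on
that pair's training samples only, for use by one-vs-one classifiers.

## The stacked ensemble

Each descriptor's block is standardized (training mean/sd), reduced, and
learned by a soft-margin kernel SVM (radial, cost 1 by default; both are
configuration). Class probabilities are a softmax over the SVM's
one-vs-one decision margins. The linear meta-classifier ("weight
allocation") is a lightly ridged multinomial logistic model over the
concatenated base probability vectors.

Two stability choices deserve explanation, because both replace a more
obvious construction that failed in testing:

* **No Platt recalibration.** libsvm's `probability = TRUE` refits a
  sigmoid by internal cross-validation; on small training sets this fit
  can *invert*, and the inverted probabilities silently flip predictions
  (observed on cleanly separable synthetic data: base test accuracy 1.0,
  stacked accuracy 0.0). The margin softmax is deterministic and
  order-faithful, and the meta stage relearns its scaling anyway.
* **Likelihood-fitted meta.** For the same reason the meta stage is a
  multinomial logistic model rather than a Platt-calibrated linear SVM:
  its argmax always agrees with the probabilities it reports, which the
  prediction contract requires (ties resolve to the earliest class in
  `class_order`).

The meta model is trained on *out-of-fold* base probabilities produced by
internal 3-fold cross-fitting, never on in-sample probabilities, so its
input distribution matches test time. The concatenated baseline
(`train_concatenated`) joins all descriptor blocks, reduces after
concatenation, and fits a single classifier — the comparison strategy the
ensemble is judged against.

**Tile aggregation.** Whole images are tiled (default 64×80 for a 256×320
image, a 4×4 grid — the tile size is configuration and the count follows
from the grid) and every tile inherits the whole-image label. At
evaluation, all tiles of an image receive the image's modal predicted
class; mode ties go to the tied class with the highest mean probability
over the image's tiles, and any residual tie to the earliest class in
class order.

## Strong versus weak cross-validation

`make_folds(mode = "strong")` assigns whole patients to folds: patients
are shuffled by seed, and each is placed in the fold where its images
least worsen per-class imbalance (then the smallest fold). Disjointness of
patients across folds is asserted on every run; a patient owning every
image of a class makes the split infeasible and raises an error naming the
patient. `mode = "weak"` stratifies images by class only, so the same
patient can appear on both sides — the leak the strong protocol exists to
prevent. Binary summaries collapse 4-class predictions by positive set
(CA alone, or CA together with TA_LG) before computing accuracy,
sensitivity, specificity and F1; ROC curves use two conventions (CA versus
all others; TA_LG among non-CA samples) with trapezoid AUC.

## The synthetic data generator

`generate_dataset()` emulates the *structure* of a multispectral
colorectal dataset, not its photorealism: balanced classes of whole images
owned by single-diagnosis patients (1–3 slides each), per-class texture
families (round blob lattice / serrated stripes / distorted tubes /
disordered fragments), VS bands with higher contrast and lower noise than
IRS bands, class-specific per-band mean spectra with the first VS and
first IRS band deliberately left flat as negative controls, patient-level
intensity/phase/orientation offsets scaled by `patient_effect_sd`, and
per-pixel Gaussian noise (`noise_sd` on VS, doubled on IRS). All
randomness flows from one root seed through per-patient and per-image
substreams, so regeneration is byte-identical; intensities are rounded to
integer camera counts so cubes round-trip exactly through 16-bit TIFF.

What passing tests on this generator show — and what they do not: the
generator produces textures that are *designed* to be separable and batch
effects that are *designed* to leak, so green results demonstrate that the
pipeline's machinery (features, folds, stacking, aggregation) behaves
correctly and in the designed direction. They say nothing quantitative
about clinical accuracy on real stained tissue, whose within-class
variability, staining artefacts and off-grid textures the generator does
not attempt to render.

## Problem sizes used by the test suite

The test suite and the acceptance checks run the full pipeline at reduced
problem sizes chosen as the package's own test conditions: cubes of
32–64 px per side, 4–39 bands, 8–12 patients with 2–3 images each, and the
fast descriptor subsets for repeated cross-validation loops (the full
six-descriptor extraction is exercised once on a 39-band cube). At these
sizes the designed effects are already unambiguous: the weak-minus-strong
accuracy gap moves from ≈0.01 (no patient effects) to ≈0.19
(`patient_effect_sd = 0.4`), and NORMAL-vs-CA strong-CV accuracy exceeds
90%.

## Known limitations

* The Tamura formulas follow one reasonable variant of each statistic;
  other published variants will give different numeric values (the
  invariances tested — transpose symmetry, constant-band conventions —
  hold for any of them).
* The BSIF bank is learned from synthetic noise images, not natural
  photographs; absolute histogram values differ from banks trained on
  photographic patches, though all contracts are bank-independent.
* Whitened band selection is provided for completeness but is expected to
  be uninformative when the whitening is fitted on the selection data
  itself (see above).
* The ensemble assumes every sample carries every descriptor; missing
  descriptors are a data error, not imputed.
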