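---
title: "Methods: segmentation, reference normalization and regularized
  discriminant classification of hemp reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Benchtop line-scan hyperspectral imaging produces, per scan, a datacube
of reflectance over two spatial axes and 462 contiguous bands between
400 and 1000 nm (about 1.3 nm resolution, roughly 0.5 mm² per pixel).
Freshly sampled hemp leaves and flowers are laid on a flat tray beside a
Spectralon-type grey panel of 20 % nominal reflectance and scanned under
halogen illumination. The analysis task is threefold: find the plant
material in each scan, convert it to per-sample relative reflectance
spectra that are comparable across scans, and classify those spectra by
cultivar, growth stage (weeks after flower initiation) or organ
(leaf/flower).

`hempspec` implements that chain with every algorithmic step exposed as
a tested function, and ships a synthetic scene/spectra generator so the
chain can be validated end-to-end without access to proprietary scans.

# Segmentation

## Contrast-optimized normalized band difference

A single gray image drives segmentation: the normalized band difference
(NBD) `(R1 - R2) / (R1 + R2)` of two band images with the higher
wavelength first. For green vegetation against a spectrally flat tray,
an NIR-vs-visible pair pushes plant pixels toward +1 and background
toward 0, and — because the two bands share each pixel's illumination
factor — the NBD is invariant to multiplicative illumination
unevenness, which is what defeats plain global thresholding of raw band
images.

The pair is not fixed a priori. `select_band_pair()` scores **every**
ordered pair (optionally on a strided band grid) by the Otsu criterion
of its NBD image — maximal between-class variance divided by total
variance over a 256-candidate threshold grid spanning the observed
range — and returns the argmax. Numerical conventions, all of which the
underlying idea leaves open:

* candidate thresholds are 256 evenly spaced values over `[min, max]`
  of the raw (not binned) values; variances are computed on the raw
  values, so an exhaustive per-candidate oracle reproduces the score
  exactly;
* score ties break toward the larger λ1, then the smaller λ2 (favoring
  NIR-vs-blue contrast);
* pixels whose NBD denominator is below `1e-6` of the cube's dynamic
  range are flagged undefined and treated as background;
* the search is meant to run once on a calibration cube and be reused
  batch-wide; `segment_scene(pair = "auto")` exists for single-scan
  use.

## Intermodes thresholding

The NBD histogram of a plant-on-tray scene is bimodal: a background
mode near 0 and a vegetation mode near +1. `intermode_threshold()`
histograms the values into 256 bins (a conventional 8-bit-like
resolution; configurable), then smooths the counts with a 3-point
moving average until the histogram is bimodal, and returns the midpoint
of the two peak positions. Conventions chosen here:

* *bimodal* means exactly two strict local maxima after collapsing
  runs of equal counts (a plateau counts once, located at its center);
  a boundary run with a single lower neighbour is a peak;
* the smoothing window is zero-padded past the histogram ends, and
  summation runs left to right, so a naive loop implementation
  reproduces every iteration bit for bit (this equivalence is asserted
  in the tests on 100 random mixtures);
* failure to reach bimodality within `max_iter` iterations, or input
  with fewer than two distinct values, is an error rather than a
  silent fallback;
* the threshold is applied to the **raw** NBD values, not the smoothed
  histogram's bin centers.

The mask is refined by morphological opening then closing with a disk
of radius 1 px (defaults; the refinement is deliberately mild),
8-connected components below 50 px are dropped, and surviving regions
are labeled in raster order of their first pixel. The labeling is
implemented in the package because the available image library labels
4-connected components only, and diagonal leaf tips would otherwise
fragment.

## Locating the reference panel

The flat panel does not appear in the NBD foreground (its NBD is near
0, like the tray), so two localization modes exist. *roi* trusts a
configured rectangle — the recommended mode when the scanning jig is
fixed. *flatness* searches candidates (segmented regions plus bright
components recovered from the intensity image outside the plant mask,
gated on a clearly bimodal intensity split, Otsu score > 0.85) and
picks the one whose mean spectrum has the lowest coefficient of
variation, requiring CV < 0.1; vegetation spectra have CV near 1, a
grey panel near 0, so the margin is wide. No qualifying candidate
yields `NULL` rather than a guess.

# Reference-ratio spectra

Per-region spectra are arithmetic means over region pixels. Ratio
spectra divide by the panel spectrum of the *same scan* (the panel mask
is eroded by 2 px to drop bright edge pixels); the panel's nominal 20 %
is deliberately not multiplied back in, so outputs are relative
reflectance in arbitrary units.

Two ratio forms are provided. `ratio_to_reference()` divides sample
mean spectra by the panel's mean spectrum — the classical quantity
plotted in spectral figures; it standardizes the camera's spectral
response but leaves spatial illumination differences between sample and
panel positions in place. `extract_spectra(columnwise = TRUE)` instead
divides each pixel column by the panel rows of that same column before
averaging. When the panel spans the scan width (the synthetic default,
and the known remedy for line-scan non-uniformity) and illumination is
multiplicative and constant over scan time, this cancels unevenness
along the scan line *exactly*; the package asserts agreement of
same-class regions under a ±15 % field to better than 1 % on zero-noise
scenes. Columns the panel does not cover fall back to the panel's
global mean spectrum.

# Regularized linear discriminant analysis

Spectra are first standardized wavelength-wise to zero mean and unit
variance using training-set statistics only (sample convention,
denominator *n* − 1); columns with vanishing variance are floored to
sd 1 with a warning, so they transform to zeros and carry no signal.
Standardization is refit inside every cross-validation fold and every
holdout replicate — the leak-free choice.

With pooled within-class covariance S (denominator *n* − *K*), class
means μ_k and empirical priors π_k, the model is

* S̃ = (1 − γ) S + γ diag(S) — shrinkage toward the diagonal; after
  wavelength-wise standardization diag(S) is essentially the identity,
  so this reconciles the diagonal-target and identity-target
  formulations of regularized LDA;
* b_k = S̃⁻¹ μ_k, with entries of magnitude ≤ δ set **exactly** to 0
  (hard thresholding, acting as wavelength selection; the count of
  surviving coefficients is non-increasing in δ);
* score_k(x) = x′b_k − ½ μ_k′b_k + log π_k, predicted class = argmax,
  ties toward the alphabetically first class. If δ removes every
  coefficient the model degenerates, by construction, to a
  priors-only classifier.

Numerics: S̃ is never formed as a 462 × 462 matrix. With class-centered
rows Z, S = Z′Z/(n − K), and the Woodbury identity solves the
diagonal-plus-low-rank system at O(p·n²), which keeps a full tuning run
(hundreds of fits) in seconds. When γ = 0 and S is singular (n ≤ p), a
ridge of `1e-8 · trace(S)/p` stabilizes the solve — γ = 0 is inside the
search range, so this floor is part of the contract. At (γ = 0, δ = 0)
on full-rank data the predictions coincide with classic LDA, which the
tests assert against an independent implementation on 20 random
instances.

## Hyperparameter tuning

γ is searched in [0, 0.01] (high-dimensional problems favour small γ)
and δ in [10⁻³, 10³] on a log scale, minimizing stratified 10-fold CV
error; all candidates share the same seeded folds so they compete on
identical splits. The default strategy spends a 30-evaluation budget as
10 Latin-hypercube points followed by local refinement around the
incumbent with a shrinking Gaussian proposal radius. A model-based
(surrogate) optimizer could be substituted — the contract is only
"best-found pair within budget, reproducible under a seed" — and a
regular-grid fallback is built in; for a 2-D box with a broad optimum
basin, space-filling plus refinement is simple, deterministic and
empirically sufficient (separable problems reach CV error 0 well within
budget).

## Repeated-holdout validation and comparisons

Model performance is the mean over 30 replicates of test accuracy under
stratified 3:1 splits (replicate *r* uses seed `base_seed + r`; per
class, the test share is `round(0.25 · n_c)`, kept between 1 and
n_c − 2). The standard error is sd/√reps; a single replicate reports
`NA`. All test predictions are retained so confusion matrices can be
pooled over replicates and row-normalized (rows sum to 1 exactly, by
construction on counts). Scenario accuracies are compared by one-way
unpaired ANOVA with Fisher's LSD at α = 0.05:
LSD_ij = t(1 − α/2, df) √(MSE (1/n_i + 1/n_j)); compact letters come
from a sweep-and-absorb over mean-sorted groups, so all-identical
groups always share a letter and zero-variance groups (all replicates
perfect) are legal.

# Exploration

PCA operates on mean-centered, unscaled spectra (shared units across
columns; a scaling flag exists). Explained-variance fractions are
reported as percentages; each component's sign is fixed so its
largest-magnitude loading is positive, making scores reproducible under
row reordering.

# The synthetic generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's claims are validated.

**Spectra.** A class mean curve is a visible baseline (default 0.06)
plus a green reflectance bump (amplitude 0.05 at 550 nm, width 40 nm),
blended through a logistic red edge (inflection 720 nm, scale 7 nm)
into an NIR plateau (0.45), minus a chlorophyll absorption dip (depth
0.045 at 670 nm, width 20 nm). These values produce the canonical green
vegetation shape: reflectance low in the visible, a local minimum at
the 670 nm band, and the plateau reached within 5 % beyond the red
edge. Samples scatter around their class mean with independent
multiplicative Gaussian noise per wavelength (sd 0.05) — a deliberate
simplification (see limitations).

**Class structure.** Organ effects are large (flower NIR plateau +30 %,
red-edge slope +40 % relative to leaf), stage effects are monotone
(chlorophyll dip −8 % and NIR +5 % per stage step, mirroring
senescence-driven pigment loss and drying), cultivar effects are small
fixed parameter factors (±1–3 %). This reproduces the qualitative
separability ordering observed in practice — organs ≫ stages ≫
cultivars — with organ classes roughly six within-class standard
deviations apart on the plateau, and stages clearly ordered, while
cultivars overlap in PC space yet remain machine-separable. A single
`separation` scalar scales all between-class mean differences; 0
collapses every class onto one distribution (chance-level
classification), 1 is the study-like default. No quantitative
within/between-class variances were available to copy, so these
defaults were fixed once, from the qualitative constraints above, and
are exposed in the generator interface.

**Sampling design.** The default design is 5 cultivars × 5 dates × 4
replicate plants (20 plants per cultivar, 100 total), 16 leaves per
cultivar-date cell, and flower counts of 24 (CW), 21–22 (BX), 16–17
(FL58) and 16 (FL70, TJ) — 868 samples in all.

**Scenes.** Objects are ellipses (leaves) or unions of overlapping
ellipses (flowers) placed disjointly; shape realism is irrelevant to
spectra and matters only for segmentation tests, where the ground-truth
label image provides exact IoU targets. The tray is spectrally flat at
0.10, the panel flat at 0.20. Illumination is a smooth multiplicative
quadratic profile of amplitude ±15 % along the scan-line (pixel) axis —
in a line-scan geometry the lamp profile across the line is fixed while
conditions are constant over scan time, so the along-track component
defaults to 0 but is available in the design. Sensor noise is additive
(sd 0.002) plus per-pixel multiplicative (sd 0.02). Rendered scenes for
segmentation tests use 160 × 220 pixels and 60 bands; classification
tests use the full 462-band grid. Everything is bit-reproducible under
a fixed seed.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: spectrally correlated biological
variation (real reflectance deviations are smooth in wavelength, not
i.i.d. per band), water-absorption features near 970 nm, specular
highlights and shadows on curved tissue, touching or overlapping
samples, camera smile/keystone, wavelength-dependent lamp spectra, and
any radiative-transfer realism. Classification accuracies on synthetic
data validate the pipeline's mechanics and statistics, not field
performance.

# Degenerate inputs and edge rules

* Constant images: Otsu contrast and intermodes threshold are errors,
  not numbers.
* Empty foreground after area filtering: a warning condition with an
  empty region table, not a crash.
* Reference spectrum with a non-positive band: an error naming the
  wavelength.
* Classes with fewer than 2 training rows (fitting) or fewer than 4
  rows (holdout splitting): errors.
* A CV fold losing an entire class: an error rather than a silently
  skewed error estimate.

# Scope and limitations

The package classifies mean reflectance spectra only; texture and
morphology features, cascade (stage-then-cultivar) classifiers,
chemical (CBD/THC) quantification, radiometric calibration from raw
counts and in-field scanning are out of scope. Region-to-plant identity
mapping is delegated to a metadata table, since tray layouts are
study-specific. The pipeline orchestrator (`run_pipeline()`,
`scenario_matrix()`) and `scripts/acceptance.R` are the intended entry
points; a shell wrapper would be a thin veneer over these functions.
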