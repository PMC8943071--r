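---
title: "Millimeter-wave skin-lesion imaging: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Millimeter-wave skin-lesion imaging: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmmwi)
```

## The problem

High-resolution millimeter-wave imaging probes skin lesions with an
ultra-wide 12–110 GHz reflection measurement: at each position of a small
raster scan, a monostatic antenna records the complex reflection
coefficient S11 over two sub-bands (12–51 GHz and 51–110 GHz). Malignant
tissue differs from benign tissue in its millimeter-wave dielectric
properties — chiefly through water and biochemical content — so a 3-D
reflectivity image reconstructed from these sweeps carries diagnostic
contrast that statistical feature extraction and classification can
exploit. This package implements that full analysis chain together with a
physics-informed synthetic cohort generator, so that every stage is
testable end to end without clinical data.

## Forward model and synthetic cohort

Tissue is modeled as a stack of single-pole Debye media,

$$\varepsilon(f) = \varepsilon_\infty + \frac{\Delta\varepsilon}{1 + i\,2\pi f \tau} - i\,\frac{\sigma_s}{2\pi f \varepsilon_0},$$

under the $e^{+i\omega t}$ convention (so $\mathrm{Im}\,\varepsilon \le 0$
for passive media; the same convention is used consistently in the
reconstruction). Default layer parameters (epidermis
$\varepsilon_\infty=3.5,\ \Delta\varepsilon=25,\ \tau=6.9\,\mathrm{ps},\
\sigma_s=0.5\,\mathrm{S/m}$, 0.1 mm; dermis $4.0/32.0/6.9/0.9$, 1.5 mm;
subcutaneous fat $2.5/5.0/8.0/0.05$, semi-infinite) sit inside the ranges
published for human skin in the microwave/millimeter-wave dielectric
literature. They are a plausible stand-in, not a claim of fidelity to any
specific measurement — the clinical study this emulates published no
dielectric values.

A lesion is a lateral disc whose tissue replaces the top of the dermis down
to the lesion depth. Malignant lesion media carry a configurable fractional
increase (`contrast`, default 0.3) in $\Delta\varepsilon$ and $\sigma_s$
relative to benign lesion tissue, reflecting the elevated water content of
tumors; per-lesion lognormal jitter (sd 0.05) provides within-class
variability. The per-position sweep is the exact plane-wave
transmission-line response of the local layer stack (impedance recursion;
verified in tests against the closed-form Fresnel coefficient and a
brute-force 50-bounce multiple-reflection series), plus additive circular
complex Gaussian noise with standard deviation `noise_level` (default 0.02)
times the mean reflection magnitude. The cohort generator reproduces the
study composition — 136 validated lesions (93 benign across five subtypes,
43 malignant/premalignant across four) plus 10 artifact-bearing scans —
with body-site classes drawn from the study's per-class distribution, and is
byte-deterministic given its seed.

What the generator deliberately does *not* emulate: antenna patterns and
near-field illumination structure, curved skin surfaces, lateral texture
within a lesion, patient motion, and VNA systematic errors. Lateral
information in a simulated scan therefore comes only from the
lesion/background footprint dichotomy, which is exactly the contrast the
classification chain needs; passing tests show the chain recovers planted
dielectric contrast under this idealization, not that it would survive
every artifact of real measurements.

Interference artifacts are emulated as narrow multiplicative notches
(triangular, 3 samples wide, default depth 0.9, i.e. a ~20 dB dip) at
random band/position/frequency locations, matching the "obvious spectral
dips" that invalidated 10 of the study's 146 measurements.

## Sub-band synthesis and validity filtering

Each position's two sub-band sweeps are calibrated to reflectivity — the
ratio of reflected to incident fields, realized against an ideal
metal-plate reference that also removes the standoff phase — and placed
adjacent in the frequency domain. The two samples at the shared 51 GHz
junction are averaged: averaging is the symmetric, continuous choice, and
the merged grid then carries a single value there, so the synthetic span is
exactly 98 GHz.

The validity filter computes each magnitude spectrum's running-median
baseline (window 11 samples) and flags a lesion invalid when any spectrum
dips more than 6 dB below that baseline over a run narrower than 5 samples.
Both comparisons are strict, so a dip of exactly 6 dB survives. The 6 dB /
5-sample defaults operationalize "obvious" narrow interference dips; they
are exposed as parameters. At these defaults the filter separates the
injected artifacts from clean sweeps with margin: injected notches are
~20 dB deep, while the 2% measurement noise can only produce sub-dB
excursions.

The scan spacing question has no single answer: the half wavelength is
1.499 mm at 100 GHz (matching the 1.5 mm increment) but 1.363 mm at the
110 GHz band edge. `max_nyquist_spacing()` computes $c/2f$ for any
reference; the package treats 100 GHz as the default reference and reports
both in the geometry summary.

## Image reconstruction

`reconstruct_cube()` is frequency-domain matched-filter back-propagation:
voxel $v$ accumulates
$\sum_p \sum_f S(f,p)\, e^{+2 i k(f) d(p,v)}$ with the free-space
wavenumber along the antenna–surface segment and the dispersive tissue
wavenumber $k(f) = 2\pi f \sqrt{\varepsilon(f)}/c$ below the surface; the
voxel value is the accumulated magnitude. The propagation path is a
straight ray split proportionally at the surface; refraction is ignored
(near-field, small angles — a documented limitation). Lateral voxels sit at
the scan positions; the depth axis is sampled at $c/(4 B \sqrt{\varepsilon'})$
(twice-oversampled range resolution), giving 8 × 6 × 20 ≈ 1000 intensity
values per cube at the default geometry.

Two numerical choices deserve explanation:

* **Phase-only focusing by default.** Using the full complex $k$ in the
  exponent gives deep voxels exponential gain that exactly offsets tissue
  attenuation. At skin-like loss over 12–110 GHz that gain reaches orders
  of magnitude within a few millimeters and amplifies noise and clutter
  faster than any signal, producing reflectivity that *grows* with depth —
  the opposite of the behavior the depth-truncation stage is built on.
  The default therefore uses only $\mathrm{Re}\,k$ (dispersive phase
  delay); `attenuation_compensation = TRUE` restores the literal complex-k
  accumulation for study.
* **Hann window before accumulation** suppresses range sidelobes of the
  98 GHz band. Tests that check the closed-form range resolution
  $c/(2B\sqrt{\varepsilon'})$ disable it, since the closed form describes
  the unwindowed response.

`das_reference()` is an independent time-domain delay-and-sum
implementation (direct inverse DFT to a fine time grid, per-voxel two-way
delays, linear interpolation, coherent sum) used as a cross-check: on
constant-permittivity point-target scenes both methods must locate the same
peak voxel, and they are held to that in the acceptance tests. It is
deliberately kept in plain R with different numerics from the compiled
frequency-domain kernel.

## Penetration depth

As depth grows the desired echo weakens and clutter dominates, so cubes are
truncated before feature extraction. Around two lateral spots — lesion
center and lesion margin — the 30 nearest depth columns are averaged into a
mean profile $p(z)$; the profile's own depth-average serves as its
threshold; the region depth is the deepest sample down to which $p$ stays
at or above threshold (ties survive, so constant cubes keep full depth);
the two region depths are averaged and the cube is cropped there (at least
one slice is always kept). Because the threshold is derived from the same
values, the estimate is invariant under positive scaling, and the
"30 columns" are taken as the nearest lateral points rather than along one
axis — the default 8 × 6 aperture has only 8 positions per axis, so a
30-column axial range cannot exist there. Aggregating columns by sum
instead of mean rescales profile and threshold together and provably yields
the same depth; both spellings are accepted for transparency.

## Two-stage 3D-PCA

The feature extractor unfolds every cube into per-lateral-point depth
profiles (linearly resampled to a common 20 samples, because truncation
leaves unequal depths), fits a PCA on the pooled point × depth matrix, and
keeps the smallest number of depth modes whose explained-variance ratios
cumulatively exceed 80% (strictly). Each lesion's per-point scores are then
concatenated into one row, and a second PCA across lesions reduces those
rows to `k_final = 6` features. This two-stage reading of "decompose the
per-point depth structures, then combine scores and loadings over all
points" yields exactly six features per lesion while honoring the per-point
depth decomposition; a one-stage PCA on fully flattened cubes is available
(`scheme = "flat"`) for comparison. PCA is computed by SVD of the centered
matrix; ratios are normalized squared singular values; each loading column
is sign-fixed so its largest-magnitude element is positive, making results
deterministic across platforms. Projection of new lesions applies training
means and loadings only — during cross-validation the held-out lesion never
touches the fit, and a deliberately leaky variant exists solely so tests
can demonstrate the guard matters.

## Classifier evaluation

Five families are evaluated: LDA (Gaussian posterior), KNN (malignant
fraction among the K nearest neighbors, K ∈ {1,3,5,7}), linear and Gaussian
SVM (margin factor C on a 0.1-step grid up to 4; Platt-calibrated sigmoid
fitted on training folds by the SVM backend), and a multilayer perceptron.
The MLP architecture is not specified by the study; the package uses one
hidden layer of 10 logistic units, weight decay $10^{-4}$, at most 2000
iterations, and a fixed per-fold seed. The Gaussian kernel width uses the
median heuristic on pairwise training distances. All scores are malignancy
probabilities in [0, 1].

Evaluation is leave-one-out cross-validation with the entire feature
pipeline refit per fold. ROC curves place thresholds at every distinct
score plus the extremes; the trapezoidal AUC then equals pairwise
concordance with ties counted one half (asserted to 1e−12 against a
brute-force loop). Operating points maximize the Youden index with ties
broken toward sensitivity; the "±" uncertainties attached to search results
are standard deviations over 200 stratified bootstrap resamples of the LOO
scores. The subset search evaluates every nonempty PC mask (63 for six
features) per family and hyperparameter, sharing the per-fold features
across all configurations, and breaks AUC ties toward fewer components,
then lexicographic masks.

Learning-curve extrapolation follows the random-repeated-sampling scheme:
stratified subsets at several sizes, mean LOO error per size, and a least
squares fit of $e(n) = a + b\,n^{-\alpha}$ with $a \ge 0$; the asymptote
$a$ is the extrapolated error. Because a flat curve leaves $(a,b,\alpha)$
unidentifiable (the power term is nearly constant over any finite size
range), the fit keeps the power law only when it beats the constant model
in an F-test at the 0.95 level and otherwise reports the observed plateau.
ROC curves are compared by stratified bootstrap of the AUC difference
(two-sided p; paired resampling when both results score the same lesions,
so a curve compared with itself gives p = 1). Repeat-sweep reproducibility
is summarized as the per-frequency variance of the magnitude spectrum as a
percent of its squared mean, plus the stability of the spectral-minimum
position.

## Problem sizes and verification scope

The test suite runs the full 146-lesion cohort through generation and
validity filtering, and verifies the classification chain on 24-lesion
cohorts (12 benign / 12 malignant, 64 frequency points per sub-band) at
three contrast levels across 20 seeds each: mean LOO AUC is required to be
monotone in contrast, above 0.95 at the default contrast 0.3, and within
three standard errors of 0.5 at zero contrast. These sizes keep the whole
suite comfortably within a desk-scale run while leaving every stage
exercised at the study geometry (8 × 6 aperture, 1.5 mm increment,
two sub-bands). The analysis scripts under `analysis/` run the full
136-valid-lesion evaluation, with the SVM C grid thinned in the driver
(noted there) since the full 41-point grid only multiplies runtime, not
coverage.

Known limitations, beyond the generator idealizations above: straight-ray
propagation without refraction; no antenna de-embedding or time-gating; the
clinical headline numbers of the motivating study (97%/98%, AUC 0.996)
derive from in-vivo data this package cannot reproduce — what the synthetic
pipeline demonstrates is that the machinery recovers planted contrast and
that every computational claim that can be checked at desk scale holds.
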