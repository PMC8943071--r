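# hrmmwi

Analysis pipeline for ultra-wideband millimeter-wave diagnostic imaging of
skin lesions, with a physics-informed synthetic cohort generator.

## The problem

Millimeter-wave imaging probes skin with a monostatic raster scan: at each
of 8 × 6 positions (1.5 mm increment, a 14.5 × 15.5 mm illuminated area),
an antenna records the complex reflection coefficient S11 over two
sub-bands, 12–51 GHz and 51–110 GHz, which are synthesized into a single
98 GHz-wide spectrum per position. Because malignant tissue differs from
benign tissue in its millimeter-wave dielectric properties, a 3-D
reflectivity image reconstructed from these sweeps carries diagnostic
contrast. The analysis chain implemented here:

1. **Cohort simulation** — layered single-pole Debye skin phantoms
   (`ε(f) = ε∞ + Δε/(1 + i2πfτ) − iσs/(2πf ε0)`) with an embedded lesion
   disc; exact transmission-line reflection per scan position; complex
   Gaussian measurement noise; narrow interference notches injected into a
   chosen number of scans (`generate_cohort()`).
2. **UWB synthesis and validity** — metal-plate reflectivity calibration,
   sub-band concatenation with junction averaging (`synthesize_uwb()`), and
   rejection of lesions whose spectra contain narrow dips deeper than 6 dB
   below a running-median baseline (`validity_filter()`).
3. **Reconstruction** — dispersive frequency-domain back-propagation
   `Σ_p Σ_f S(f,p) exp(+2ik(f)d)` with `k(f) = 2πf√ε(f)/c` (compiled
   kernel), cross-checked by an independent time-domain delay-and-sum
   implementation (`reconstruct_cube()`, `das_reference()`).
4. **Penetration depth** — two-region (lesion center/margin) 30-column
   profile thresholding and cube truncation (`estimate_depth()`,
   `truncate_to_depth()`).
5. **3D-PCA features** — depth-profile PCA with 80% explained-variance
   selection, then a second PCA across lesions to six components
   (`extract_features()`, `project_features()`).
6. **Classification** — LDA, KNN (K ∈ 1,3,5,7), linear/Gaussian SVM
   (margin factor grid), and an MLP, searched over all 63 PC subsets under
   leave-one-out cross-validation with per-fold PCA refits; malignancy
   scores, ROC/AUC, Youden operating points, per-subtype accuracies at the
   0.5 cutoff, learning-curve extrapolation `e(n) = a + b·n^(−α)`, and
   bootstrap ROC comparison (`search_pc_combinations()`, `loocv()`,
   `rrs_extrapolate()`, `compare_roc()`).

## Worked example

```r
library(hrmmwi)

cohort <- generate_cohort(seed = 1)        # 146 scans, 10 with artifacts
tab <- cohort_validity(cohort)
sum(tab$valid)
#> [1] 136

valid <- tab[tab$valid, ]
cc  <- cohort_cubes(cohort, scan_ids = valid$scan_id)  # reconstruct + truncate
src <- feature_source(labels = valid$class, cubes = cc$cubes, k_final = 6)

cv  <- loocv(classifier_config("LDA", mask = rep(1, 6)), src, seed = 1)
roc <- roc_curve(cv)
roc$auc
#> [1] 1
confusion_at_cutoff(cv)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1
```

136 of the 146 simulated scans survive the spectral-dip filter (the 10
notch-bearing scans are rejected), and at the generator's default
malignant-versus-benign dielectric contrast of 0.3 the leave-one-out AUC on
the 136 validated lesions is 1.0 — the planted contrast is fully recovered.
Lowering `contrast` toward 0 degrades the AUC toward chance, which the test
suite checks quantitatively (monotonicity over three contrast levels and
twenty seeds).

The numbered scripts under `analysis/` run the same stages over the full
cohort and write their tables to `results/` (cohort summary, validity,
depths, PCA variance ratios, the classifier × PC-subset search table,
learning curve, reproducibility variance).

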