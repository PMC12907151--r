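# ramancell

Label-free phenotyping of single cells from confocal Raman
microspectroscopy, built around one concrete use case: discriminating a
pediatric glioblastoma stem-cell line (SF188-like neurospheres) from
adult-derived glioblastoma lines by their vibrational fingerprints in
the 600–1800 cm⁻¹ region. The package is aimed at spectroscopists and
computational biologists who need a tested, leakage-controlled pipeline
from raw single-cell spectra to a held-out classification report — and
at method developers who need a realistic synthetic cohort to validate
such pipelines when no instrument data are available.

## What it does

**Preprocessing.** Raw spectra I(ν) on a common wavenumber grid
(316 channels, 3.8 cm⁻¹/pixel) are cleaned in a fixed order:

1. *Despiking* — cosmic-ray pixels are channels whose first differences
   are extreme on both sides under the modified z-score
   z = 0.6745 (d − median d)/MAD(d) with threshold 6; they are replaced
   by the local median.
2. *Rubber-band baseline* — the broad fluorescence background is the
   lower convex hull of (ν, I), anchored at both ends and interpolated
   linearly between hull vertices; it is subtracted.
3. *Fluorescence rejection* — a spectrum is discarded when the baseline
   carries more than 90 % of its total intensity.
4. *Vector normalization* — each spectrum is scaled to unit Euclidean
   norm, so only relative band intensities remain.

**Band analysis.** Class mean ± SD profiles, subtraction spectra
(pediatric − adult), and Savitzky–Golay negative second derivatives
(window 9, order 3, units per cm⁻²) with peak picking by topographic
prominence and assignment to a packaged 35-band literature table
(621–1745 cm⁻¹: nucleic-acid, protein, lipid, carbohydrate and
cytochrome/NADH bands).

**Classification.** A balanced cohort (equal spectra per class) is
split 80/20 with all spectra of a physical cell on one side. Features
are standardized and reduced to 20 principal components — both fitted
on the training partition only — and classified by a small multilayer
perceptron (default 5 hidden layers × 5 ReLU neurons, Adam, early
stopping), with pediatric-class probability scores for ROC analysis.
A grouped, stratified 10-fold cross-validation over 1–10 layers and
2–100 neurons per layer is available for architecture search. The
held-out report gives the row-normalized confusion matrix, accuracy,
sensitivity (pediatric recall), specificity, precision, per-class F1
and midrank ROC AUC.

**Synthetic cohorts.** `simulate_cohort()` draws a full study — six
cell lines (one pediatric), three points per cell, 1,382 spectra of
which 364 are pediatric — as Lorentzian band superpositions with
hierarchical brightness effects, per-spectrum biochemical-composition
variability, class-specific band contrasts, fluorescence baselines,
detector noise and cosmic-ray spikes, returning the exact additive
ground truth of every spectrum for oracle testing.

## Worked example

```r
library(ramancell)

cohort  <- simulate_cohort(synthetic_config(), seed = 42)
spectra <- preprocess_spectra(cohort$spectra)
dplyr::count(qc_log(spectra), kept)
#>   kept      n
#> 1 FALSE    17
#> 2 TRUE   1365

fit <- run_raman_pipeline(synthetic_config(), seed = 42)
fit
#> Raman classification pipeline (seed 42)
#> PCA: 20 components, 91.41% variance retained | MLP: 5x5x5x5x5
#> Held-out classification report (positive class: pediatric)
#>                  Predicted pediatric Predicted adult
#> Actual pediatric                93.1             6.9
#> Actual adult                     0.0           100.0
#> accuracy 96.6% | sensitivity 93.1% | specificity 100.0% | AUC 0.988
#> F1 pediatric 96.4% | F1 adult 96.7% | n_test 72 + 74
```

Of the 1,382 simulated spectra, 17 are rejected as fluorescence-
dominated or spike-damaged. The classifier then sees a balanced cohort;
the printed report refers to the 146 held-out spectra from cells the
model never saw: 93 % of pediatric test spectra are recognized, no
adult spectrum is mislabelled, and the ROC AUC of 0.988 summarizes
separability across all thresholds. `glance(fit)` returns the same
numbers as a one-row tibble, `tidy(fit)` as a metric table, and
`autoplot(fit$report)` draws the ROC curve.

Band attribution on the same data:

```r
prof <- class_profile(spectra, "pediatric")
d2   <- neg_second_derivative(prof$mean, prof$wavenumber)
assign_bands(detect_peaks(d2, prof$wavenumber))
#> # A tibble: ... position height band allocation            distance
#> 1      620. 0.000238  621 Phosphate backbone (DNA/RNA)        1.37
#> 2      644. 0.000182  643 Tyrosine (ring breathing)           1.11
#> 3      672. 0.000276  672 Phosphate backbone (DNA/RNA)        0.330
#> ...
```

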