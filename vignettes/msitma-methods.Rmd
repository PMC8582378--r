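---
title: "Classifying tissue-microarray MALDI-MSI spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissue-microarray MALDI-MSI spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MALDI mass spectrometry imaging (MSI) of a tissue microarray (TMA) yields
one tryptic-peptide mass spectrum per spatial pixel, hundreds of spectra
per patient tissue core. The clinical question is per *sample*: is this
patient's tissue tumour or normal; does this primary tumour carry lymph
node metastases? `msitma` implements a complete supervised pipeline for
this setting:

1. read continuous-mode imzML datasets and a pixel-level annotation table;
2. aggregate each patient's spectra of one tissue type into a *tissue
   group* — the unit of classification ("one tissue group is one sample");
3. harmonize all datasets onto one m/z bin grid, with optional total-ion-
   count (TIC) normalization and a square-root transform;
4. train two neural classifiers per cross-validation fold and average
   their per-spectrum confidences;
5. fuse each validation group's spectrum confidences by their median and
   threshold at 0.5;
6. report accuracy, balanced accuracy, sensitivity, specificity and AUC
   per fold, plus per-group accuracies, aggregated as unweighted means
   over folds.

A seeded synthetic cohort generator emulates the relevant structure of
real TMA cohorts so that every stage, and the package's acceptance
experiments, run without any external data.

## Preprocessing model

**Tissue groups.** The annotation table maps `(tma_id, x, y)` pixels to
`(patient_id, group_id, label)`. Every annotated spectrum lands in exactly
one group; unannotated pixels are excluded and counted. A pixel claimed by
two groups, or a group with two patients or two labels, is a fatal
consistency error rather than a warning: silent relabelling is how
leakage and label noise enter cohort studies.

**Binning.** Different TMAs are acquired with slightly different axes
(at real scale, 171,099–171,178 points, minima within ~0.4 Da of each
other, similarly for the maxima). A single grid is computed from the
global extremes over all datasets: with bin width `w` the bin count is
`B = round((max − min) / w)`, and `B` bin centers are linearly spaced
over `[min, max]` inclusive. Each m/z point is assigned to its nearest
center and intensities are summed per bin, so each spectrum's total ion
count is conserved exactly. Choices worth stating:

* *Rounding.* `round`, not `ceiling`: at width 3 with the real-cohort
  extremes the range/width ratio is ≈ 1232.36, and the nearest-integer
  rule reproduces the 1232-feature space the downstream architectures
  assume.
* *Ties.* A point exactly halfway between two centers goes to the
  lower-index bin — deterministic and independent of input order.
* *Out-of-range points.* Clamped to the end bins rather than dropped,
  preserving conservation in the presence of axis jitter.
* *TIC normalization* divides by the spectrum total so it sums to 1.
  Vendor exports are often already TIC-normalized, hence the flag to
  disable. All-zero spectra (tissue voids) are dropped with a count.
* *Square root* per bin compresses the dynamic range — mean bin intensity
  is much higher at low m/z — which speeds convergence of the
  gradient-trained models. It is monotone, so within-spectrum ordering is
  untouched.

## The classifiers

Both networks map a binned spectrum (length `B`) to a sigmoid confidence
in `[0, 1]` and are trained with mini-batch stochastic gradient descent
(batch 512, momentum 0.9) on binary cross-entropy, with fixed
learning-rate schedules and no early stopping; with a fixed seed a rerun
is bit-identical.

**Multilayer perceptron.** Hidden layers of 1024 and 512 rectified-linear
units with biases, one sigmoid output; 20 epochs at rate 0.01 then 10 at
0.001; the positive class is weighted 2.5× in the loss. At `B = 1232`
this is exactly 1,787,905 trainable parameters.

**1-D convolutional network.** Twelve convolution layers, kernel 9, no
biases; strides 4 (layer 1), 3 (layers 6 and 10), 1 otherwise; filters
(32, 16, 16, 16, 16, 32, 32, 32, 32, 32, 64, 1). Layers 1–11 are preceded
by batch normalization (2 trainable parameters per input channel), layers
2–12 additionally by ReLU; global average pooling and a sigmoid follow
layer 12, making the network length-agnostic. Schedule: 5 epochs at 0.1,
5 at 0.01, 1 at 0.001, weight decay 0.001 per layer, no class weighting.
Exactly 72,802 trainable parameters, independent of `B`.

The filter list deserves a note: stated descriptions of this architecture
can be read several ways, but only the reading above — 16 filters on
layers 2–5, 32 on layers 6–10, and batch normalization before layers 1–11
only — enumerates to 72,802; normalizing before all 12 layers would give
72,930. The package treats the parameter count as the architecture's
checksum, and `count_trainable_params()` enumerates it analytically.

Further numerical choices (the reference training framework's defaults):
batch-normalization epsilon 1e-3, running statistics updated with rate
0.1 and used at inference; weight decay applied to convolution kernels
only, not to normalization scale/shift; plain (non-Nesterov) momentum;
He-normal weight initialization. Both member networks and the epoch
shuffles derive their seeds from the fold seed.

**Ensemble and fusion.** The per-spectrum confidence is the mean of the
two members' outputs. A tissue group's decision is the *median* of its
spectra's confidences, thresholded at 0.5 (strictly below ⇒ negative; at
or above ⇒ positive — the boundary value is positive, and an even count
takes the mean of the two middle values). The threshold is deliberately
not optimized.

## Cross-validation designs

* **Leave-one-TMA-out** — one fold per TMA, validating all its groups;
  appropriate when every patient sits on one TMA, and fatal (by
  assertion) otherwise. This simulates deploying the model on a newly
  acquired array.
* **Balanced k-fold** — each fold validates exactly `n_per_class`
  randomly drawn groups per class (default 10 + 10, 10 folds), drawn
  independently per fold so a scarce class (e.g. 42 positive groups
  against 100 validation slots) recurs across folds; the training side
  excludes every group of every validated patient.

Both constructors assert patient-disjointness on every split, and
`run_cross_validation()` re-asserts it before training each fold.
Per-spectrum AUC uses the exact Mann–Whitney rank formula with ties
counting ½, which is algebraically identical to enumerating all
positive–negative pairs — the test suite checks the equality exactly,
not to a tolerance. Fold metrics are aggregated as unweighted means over
folds (not pooled over spectra).

One subtlety of the balanced design: folds are constructed independently,
so validation groups of *other* folds remain in a given fold's training
set — with only 42 positive groups and 100 validation slots they cannot
all be excluded simultaneously. Each fold on its own is leakage-free.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` emulate, per TMA: an evenly spaced
m/z axis whose two extremes are jittered uniformly (so dataset extremes
differ across TMAs, exercising harmonization); spectra that are sums of
shared Gaussian peaks whose expected amplitude decays exponentially with
m/z; per-pixel log-normal amplitude noise per peak and a small half-normal
additive baseline; patients carrying negative and/or positive cores with
variable spectra per core; and a configured subset of peaks whose
amplitude is multiplied by a fold change in positive-class pixels. Peak
positions are drawn uniformly subject to a 4-sigma minimum separation
(so each peak is a resolvable local maximum of the class-mean spectrum).

Desk-scale defaults, chosen once as this package's study conditions: 2000
axis points over 800–1100 Da (the same sampling density matters less than
the peak/bin geometry; ~100 bins at width 3), axis jitter 0.4 Da (below
half the default bin width), 40 peaks of sigma 1.2 Da, amplitude decay
scale 150 Da, noise sdlog 0.3, baseline 2% of the mean peak amplitude,
4–8 spectra per core. The acceptance experiments use 6 TMAs × 20 patients
(2 normal + 4 tumour cores each) with fold change 3 at 10 peaks — about
4,300 spectra, sized so the full leave-one-TMA-out experiment (12 network
trainings) completes in a few minutes on one CPU.

What the generator does *not* emulate — and hence what passing recovery
experiments do and do not show: isotope envelopes, matrix clusters,
calibration drift, baseline curvature, spatial within-core gradients, and
patient-level biological heterogeneity beyond the core-level noise model.
A fold-change-3 signal at 10 of 40 peaks is deliberately easy; recovery
there validates the pipeline's plumbing (no leakage, correct fusion,
calibrated thresholding), not clinical-grade discrimination on real
tissue. The companion null experiment (fold change 1) checks the
opposite direction: cross-validated AUC stays at chance, i.e. the
pipeline cannot hallucinate class structure that is not there.

## Degenerate inputs and edge rules

* Empty imzML files read as empty collections; a missing `.ibd`, a
  length-mismatched pixel, or a non-increasing axis is an error naming
  the file or pixel.
* A single-bin grid puts its center at the range midpoint; a degenerate
  range (max ≤ min) is an error.
* Training requires ≥ 2 rows and both classes; predicting with a
  mismatched column count is an error, as is a threshold outside [0, 1].
* AUC on a one-class fold is `NA` with a warning; the other metrics are
  still returned.

## Known limitations

* The training schedules are fixed by specification. At cohort sizes well
  below one batch (512 spectra) they yield few gradient updates, so
  confidences rank correctly (AUC ≈ 1 on separable data) long before they
  are calibrated; the thresholded group accuracies are meaningful at the
  acceptance-experiment scale and above.
* The imzML layer writes and reads the continuous dialect only;
  processed-mode files with per-pixel axes are out of scope.
* No peak picking, recalibration, baseline subtraction or adaptive
  binning: inputs are assumed baseline-corrected, and the bin grid is
  deliberately uniform.
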