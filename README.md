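# msitma

Supervised classification of MALDI mass-spectrometry-imaging (MSI) tissue
microarrays (TMAs), for proteomics groups who want per-*sample* (per
patient tissue group) diagnostic calls from per-*pixel* tryptic-peptide
spectra — e.g. tumour vs. normal colorectal tissue, or lymph-node
metastasis status predicted from primary endometrial tumours.

The pipeline, end to end:

1. **I/O** — read continuous-mode imzML/ibd imaging datasets and a
   pixel-level annotation table; aggregate each patient's spectra of one
   tissue type into a labelled *tissue group* ("one tissue group is one
   sample"); optional total-ion-count (TIC) normalization.
2. **Featurization** — one linear m/z bin grid over the global extremes of
   all datasets (`B = round(range / width)` bins, width 3 Da by default;
   the real-cohort extremes 799.757…–4496.840 Da give B = 1232),
   nearest-bin intensity summation (conserves each spectrum's total ion
   count exactly), then an elementwise square root to compress the dynamic
   range.
3. **Models** — two fully specified neural classifiers, trained per fold
   and fused by averaging their sigmoid confidences:
   a multilayer perceptron (1024 and 512 ReLU units, biases, positive
   class weighted 2.5; 1,787,905 trainable parameters at B = 1232) and a
   12-layer 1-D convolutional network (kernel 9, no biases, strides
   4/3/3 at layers 1/6/10, filters 32,16,16,16,16,32,32,32,32,32,64,1,
   batch normalization before layers 1–11, global average pooling;
   72,802 parameters regardless of B). Both train with SGD (batch 512,
   momentum 0.9) on binary cross-entropy under fixed learning-rate
   schedules.
4. **Decisions** — per-spectrum confidences are fused per tissue group by
   their **median** and thresholded at 0.5 (below ⇒ negative).
5. **Validation** — leave-one-TMA-out or balanced k-fold designs, both
   with an always-on patient-disjointness assertion; per-fold accuracy,
   balanced accuracy, sensitivity, specificity and AUC (exact
   Mann–Whitney ranks, ties ½), plus per-group accuracies, averaged
   (unweighted) over folds.
6. **Synthetic cohorts** — a seeded generator of imzML-writable TMA
   cohorts with Gaussian peptide-like peaks, m/z-decaying amplitudes,
   per-TMA axis jitter, log-normal noise and configurable
   class-discriminating peaks, so everything above runs and is tested
   with no external data.

## Worked example

A colorectal-style synthetic cohort — 6 TMAs, 20 patients each with 2
normal and 4 tumour cores, a fold-change-3 signal at 10 of 40 peaks —
pushed through the full leave-one-TMA-out evaluation (12 network
trainings; a few minutes on one CPU):

```r
library(msitma)

cfg <- sim_config(n_tmas = 6, patients_per_tma = 20,
                  spectra_per_core = c(4, 8),
                  fold_change = 3, n_effect = 10, seed = 1)
cohort <- generate_cohort(cfg)
print(cohort)
#> <sim_cohort> 4282 spectra on 6 TMAs; 120 patients, 240 groups; 40 peaks (10 discriminating, fold 3); seed 1

groups <- assign_groups(cohort$spectra, cohort$annotation, quiet = TRUE)
fm <- build_feature_matrix(groups, width = 3)
print(fm)
#> <msi_features> 4282 spectra x 100 bins (240 groups, 120 patients, 6 TMAs); TIC on, sqrt on

cv <- run_cross_validation(groups, design = "loto", seed = 1)
print(cv)
#> <msi_cv> loto design, 6 folds, threshold 0.50, seed 1
#> mean over folds: accuracy 0.9998 | balanced 0.9998 | AUC 1.0000 | group accuracy 1.0000

print(cv$folds[, c("split_id", "n_val_spectra", "n_val_groups",
                   "auc", "group_accuracy")], row.names = FALSE)
#>  split_id n_val_spectra n_val_groups auc group_accuracy
#>     tma01           727           40   1              1
#>     tma02           713           40   1              1
#>     tma03           688           40   1              1
#>     tma04           713           40   1              1
#>     tma05           722           40   1              1
#>     tma06           719           40   1              1
```

Reading: every held-out TMA's spectra are ranked essentially perfectly
(AUC 1.0), per-spectrum thresholding at 0.5 is right for 99.98% of
pixels, and after median fusion all 240 tissue groups across the six
folds are classified correctly. Re-running the same configuration with
`fold_change = 1` (no class signal) drives the mean cross-validated AUC
to ≈ 0.52 — chance level — confirming the pipeline finds nothing when
there is nothing to find.

The same objects are reachable from the shell via the thin dispatcher
`inst/cli/msitma` (`simulate`, `featurize`, `crossval` subcommands, one
YAML config), and `vignettes/msitma-methods.Rmd` documents the models,
parameter choices and limitations.

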