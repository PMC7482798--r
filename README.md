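# immunoPET

Noninvasive estimation of a tumor immune profile from FDG-PET images of
lung adenocarcinoma, for imaging scientists and translational oncology
groups working on immunotherapy biomarkers.

Checkpoint-blockade response depends on the tumor immune
microenvironment, but tissue biomarkers sample one lesion of many.
immunoPET implements a whole-pipeline alternative: predict the
**cytolytic activity score**

> CytAct_s = mean( z(log2 GZMA)_s , z(log2 PRF1)_s )

— a two-gene RNA-seq signature of cytotoxic T-cell activity — directly
from the FDG uptake pattern of each lesion, then turn per-lesion
predictions into patient-level biomarkers for immune checkpoint blockade
(ICB).

The pipeline:

1. **Segmentation** — semi-automatic adaptive threshold
   `T = β·I70 + I_background` (β = 0.3; I70 = mean uptake of seed-box
   voxels above 70% of the box maximum), 26-connected component of the
   maximum; conventional features (SUVmax, SUVmean, MTV) on the side.
2. **Cubes + augmentation** — a 64 mm cube (32³ voxels at 2 mm) around
   the lesion centroid, max-normalized; training-time augmentation by
   three-axis random rotations in [0°, 90°], fifteen copies per lesion.
3. **3-D CNN regression** — a compact convolutional network (stride-2
   average-pool stem; 3 conv blocks of 4/8/16 channels; global average
   pooling; linear head) trained with MSE/Adam under 10-fold
   cross-validation; every lesion gets one pooled out-of-fold prediction.
4. **Biomarkers** — RECIST 1.1 target-lesion floors (nodes ≥ 15 mm short
   axis, others ≥ 10 mm), per-patient minimum/mean/max predicted CytAct
   and inter-lesion variance; dichotomization at a CytAct cutoff
   (default −0.107).
5. **Statistics** — Spearman correlation (exact permutation p at small
   n), Wilcoxon rank-sum (exact enumeration up to pooled n = 12),
   ROC/AUC with DeLong CI and Youden cutoff, logistic regression with a
   Firth option, Kaplan–Meier / log-rank / Cox HR.
6. **Synthetic cohorts** — a seeded phantom generator whose lesions
   encode a latent immune score in rim-to-core contrast and speckle,
   with matched two-gene expression and worst-lesion-driven ICB outcomes,
   so the full pipeline is testable without patient data.

## Worked example

A complete synthetic run — simulate phantoms, segment, score expression,
train the cross-validated CNN, aggregate biomarkers:

```r
library(immunoPET)

metrics <- runPipeline(
  list(seed = 7, folds = 5, cube_side_mm = 64,
       phantom = list(nPatients = 60, lesionProbs = 1),
       cnn = list(epochs = 2)),
  outDir = "demo_run")
str(metrics[c("pooled_oof_rho", "auc_min_cytact", "pfs_hr_high")])
```

```
List of 3
 $ pooled_oof_rho: num 0.748
 $ auc_min_cytact: num 0.82
 $ pfs_hr_high   : num 0.525
```

`pooled_oof_rho` is the Spearman correlation between out-of-fold CNN
predictions and the RNA-derived CytAct targets (0.75 here: the network
recovers the latent immune signal from uptake texture alone).
`auc_min_cytact` is the discrimination of responders by the minimum
predicted CytAct per patient, and `pfs_hr_high` the progression-free
survival hazard ratio of the high-CytAct group — below 1, i.e. high
minimum CytAct associates with slower progression.  The run directory
contains every intermediate artifact (`lesions_truth.csv`,
`pet_features.csv`, `immune_scores.csv`, `model/`, `biomarkers.csv`,
`metrics.json`) plus the resolved `config.json` that reproduces it.

Individual stages are plain functions (`segmentTumor()`, `cytAct()`,
`extractCube()`, `trainCytActCNN()`, `aggregatePatients()`, ...); a thin
CLI over them ships in `inst/cli/immunopet.R`.

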