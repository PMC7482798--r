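---
title: "Estimating tumor immune profiles from FDG-PET: models and methods"
author: "immunoPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor immune profiles from FDG-PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tissue-based immune biomarkers for checkpoint blockade (ICB) rely on a
biopsy of a single lesion, while metastatic lung adenocarcinoma presents
many lesions whose immune microenvironments differ.  FDG-PET images every
lesion at once, and tumor glucose metabolism is tightly coupled to the
immune contexture, so uptake *patterns* may carry an immune signal that
conventional PET features (SUVmax, metabolic tumor volume) do not.

immunoPET implements that idea end to end: segment each lesion with an
adaptive threshold, hand a normalized cube of uptake around the lesion to
a 3-D convolutional regressor trained against the cytolytic activity
score (CytAct) of matched tumor RNA-seq, and aggregate per-lesion
predictions into patient-level biomarkers — the minimum predicted CytAct
across lesions as the representative value, and the inter-lesion variance
as a heterogeneity measure.

## CytAct and the IFNG score

CytAct for sample $s$ is the mean of the z-scored $\log_2$ expression of
granzyme A and perforin:

$$\mathrm{CytAct}_s = \tfrac12\left(z(\mathrm{GZMA})_s +
z(\mathrm{PRF1})_s\right), \qquad
z(g)_s = \frac{g_s - \bar g}{\mathrm{sd}(g)}$$

with the sample standard deviation ($n-1$ denominator) taken across the
cohort, so cohort-mean CytAct is 0 by construction and the score is
invariant to positive affine rescaling of either gene.  Raw-scale
matrices are transformed $\log_2(x+1)$ first.  The interferon-γ score
averages six genes (IDO1, CXCL9, CXCL10, IFNG, HLA-DRA, STAT1); we
z-score each constituent before averaging so the genes contribute
comparably — the same construction as CytAct.  A `zscore = FALSE` flag
gives the plain mean for sensitivity analyses; with typical RNA-seq
dynamic ranges the two orderings are very close, but the z-scored form is
the default because a raw mean is dominated by the most abundant gene
(HLA-DRA).

## Adaptive-threshold segmentation

Segmentation is semi-automatic: the user supplies an axis-aligned seed
box around the lesion, and the threshold is

$$T = \beta \, I_{70} + I_{\mathrm{background}}, \qquad \beta = 0.3,$$

where $I_{70}$ is the mean uptake of seed-box voxels with uptake strictly
greater than 70% of the seed-box maximum, and $I_{\mathrm{background}}$
is the mean uptake in a shell (default 2 voxels) dilated around the seed
box, excluding shell voxels above the same 70% level so tumor spill-in
does not inflate the background estimate.  Voxels at or above $T$ inside
the seed box are kept, then restricted to the 26-connected component
containing the seed-box maximum.

Edge cases are handled explicitly and deterministically:

* a **uniform** volume of value $c$ yields $I_{70} = I_{\mathrm{background}}
  = c$ and $T = 1.3c$ at the default $\beta$ — above every voxel, so no
  mask; the spill-in exclusion would empty the shell here, in which case
  the unfiltered shell mean is used and the lesion flagged degenerate;
* a **single hot voxel** of value 10 on empty background gives
  $T = 0.3 \cdot 10 + 0 = 3$ and a one-voxel mask (mask inclusion uses
  $\ge T$ precisely so this defining voxel survives);
* $I_{70} \le I_{\mathrm{background}}$ raises a degeneracy warning but
  still returns $T$, leaving the decision to the caller.

The threshold is scale-equivariant (scaling uptake by $a>0$ scales $T$ by
$a$ and leaves the mask unchanged), and raising $\beta$ can only shrink
the mask.  Conventional features are computed from the mask: SUVmax,
SUVmean, and metabolic tumor volume (voxel count × voxel volume, mL).

## Cubes and rotation augmentation

The network input is a cubic patch of fixed physical size (default 64 mm,
i.e. 32³ voxels after 2 mm isotropic resampling) centered on the mask
centroid and zero-padded past the volume border.  The cube *contains* the
lesion with its surrounding context; nothing is masked out, because
peritumoral uptake is plausibly informative.  Each cube is divided by its
own maximum (`normMode = "max"`), which removes scanner scale; an
unnormalized mode is available.  Resampling is trilinear for volumes and
nearest-neighbour for masks; lattice-coincident sample points are snapped
(tolerance 1e-9) so identity resampling and right-angle rotations are
value-exact.

Training augmentation draws three independent angles uniformly in
[0°, 90°] and applies them about the z, y and x axes in that fixed order
(one composed trilinear resampling, zero fill).  Fifteen rotated copies
per lesion per epoch are used, with fresh angles at every appearance.
Augmentation copies are generated from training-fold samples only, so no
rotated view of a validation lesion ever reaches the optimizer.

## The 3-D convolutional regressor

The regressor is deliberately small: a stride-2 average-pooling stem,
three blocks of (3×3×3 convolution, same padding → ReLU → 2× max
pooling) with 4, 8 and 16 channels, global average pooling, and a single
linear output.  Loss is mean squared error, optimized with Adam
(learning rate 1e-3, batch 16) for 3 epochs per fold.  Convolutions are
implemented as im2col + BLAS matrix products in C++; a single integer
seed drives weight initialization, epoch shuffling and augmentation
angles, making training bit-reproducible on a given platform.

The capacity and schedule were fixed by a pilot on the synthetic phantom
task before the validation suite was frozen: this is the smallest
configuration that recovers the latent score reliably at single-CPU
desk scale, and every element (channels, stem factor, epochs, batch,
learning rate, augmentation count) is exposed in `cnnConfig()`.

Training uses 10-fold cross-validation with a seeded shuffle into folds
whose sizes differ by at most one.  Each lesion receives exactly one
out-of-fold prediction — the pooled internal-validation estimate — and
the pooled Spearman correlation with the targets is the headline
recovery metric.  Inference on new lesions uses the mean of the ten fold
models, which avoids a refit on the full cohort and gives a mild
ensembling benefit.

## Patient-level biomarkers

Target lesions follow RECIST 1.1 size floors: lymph nodes at
short-axis ≥ 15 mm, all other sites at long-axis ≥ 10 mm.  Per patient we
report the minimum, mean and maximum predicted CytAct and the
inter-lesion sample variance ($n-1$; undefined for single-lesion
patients, who are excluded from heterogeneity analyses).  The minimum is
the representative biomarker: under worst-lesion-driven response, the
least immunogenic lesion determines progression.  Dichotomization at a
cutoff assigns `high` to patients strictly above it, ties to `low`; the
shipped default (−0.107) is the Youden-optimal point of the reference
analysis, and `rocAnalysis()` derives a cohort-specific cutoff when one
is preferred.

## Statistics

`spearmanRho` uses midranks with an exhaustive-permutation two-sided p
for $n \le 9$ (valid under ties) and the t approximation above that.
`rankSumTest` enumerates all $\binom{m+n}{m}$ group assignments when
$m+n \le 12$ (two-sided p as twice the smaller tail, capped at 1) and
otherwise uses the normal approximation with tie and continuity
corrections.  ROC analysis reports the midrank (Mann–Whitney) AUC, a
DeLong 95% CI, and the Youden-optimal cutoff; degenerate curves (AUC 0 or
1) get a zero-width CI.  Logistic regression is plain maximum likelihood
with Wald p-values and an explicit complete-separation guard; the Firth
option maximizes the Jeffreys-penalized likelihood and stays finite under
separation.  Survival uses Kaplan–Meier curves, the two-group log-rank
test, and a Cox hazard ratio with Efron tie handling; a group with zero
events yields a flagged, undefined HR rather than a spurious estimate.
No multiple-testing correction is applied; raw p-values are reported.

## The synthetic phantom cohort

Real radiogenomic structure linking uptake texture to immune state is
unknown; the generator encodes an explicit, monotone stand-in so that
recovery is well-defined:

* each lesion is an ellipsoid (semi-axes drawn from 8–14 mm) in its own
  32³ volume at 2 mm spacing, on a noisy background (mean 0.5, sd 0.05
  SUV-like units);
* a latent immune score $u \sim N(0,1)$ sets the **rim-to-core uptake
  ratio** $e^{0.8u}$ through a smoothstep radial profile whose overall
  amplitude is held fixed — mean uptake alone is deliberately
  uninformative, the *pattern* carries the signal — and the
  **speckle amplitude** (multiplicative intralesional noise) rises
  sigmoidally with $u$, from 0.05 to 0.25;
* matched expression: GZMA and PRF1 $\log_2$ values are affine in $u$
  plus noise, so noise-free CytAct equals $z(u)$ exactly; the six IFNG
  genes are driven by a latent correlated with $u$ at a configurable
  target.

Treatment outcomes follow the worst-lesion logic: per-lesion size change
$\mathrm{pct} = a - b\,u + \varepsilon$ (defaults $a=-30$, $b=15$,
$\varepsilon \sim N(0, 8^2)$, floored at −100%), PR only when every
lesion shrinks past −30%, PD when any grows past +20%, SD otherwise;
PFS/OS are exponential proportional-hazards times with log-hazard
$-0.8\min_\ell u_\ell$ (plus an optional variance term), administrative
censoring at 24 months and 15% random early censoring.  Lesion sites are
drawn with the frequencies typical of metastatic lung adenocarcinoma
(lung and nodal lesions dominating), nodal short axes from 15–35 mm and
other long axes 10–60 mm.  A variance-linked-resistance preset
(`a = -60`, `hetPenalty = 40`, i.e. each lesion's shrinkage worsened by
40% per sd of the patient's latent scores, with the intercept deepened to
keep response rates realistic) generates cohorts in which heterogeneity
itself drives nonresponse; its strength was fixed by the same pilot as
the network schedule.

What the generator does **not** emulate: scanner point-spread and
reconstruction artifacts, respiratory motion, attenuation effects,
anatomically realistic backgrounds, inter-lesion correlation of immune
state within a patient, and any real (unknown) radiogenomic mapping.
Passing the recovery suite therefore shows the pipeline is correct and
can learn a monotone texture–score link at realistic noise levels — not
that the specific link exists in patients.

## Problem sizes and numerical choices

The validation suite trains on 300 single-lesion phantoms (32³ cubes,
10-fold cross-validation, 15 rotated copies per lesion per epoch) and
simulates twenty 40-patient multi-lesion cohorts for the biomarker and
heterogeneity analyses; these sizes keep a complete run on one CPU
comfortable while leaving the recovery signal far from the decision
boundaries.  Fold assignment, augmentation, phantom construction and
outcome draws are all governed by explicit integer seeds; sub-seeds are
derived linearly and kept inside 32-bit range.  Trilinear interpolation
snaps lattice-coincident coordinates at 1e-9; cube placement uses
floor(x + 0.5) rounding so whole-voxel lesion shifts reproduce identical
cubes (IEEE round-half-to-even would not); max-pooling breaks ties by
first index; Adam uses the standard (0.9, 0.999, 1e-8) constants.

## Limitations

The network architecture, optimizer schedule and cube size are package
choices validated on synthetic data only; applying the pipeline to real
FDG-PET requires cohort-specific retraining with matched RNA-seq, and
the shipped −0.107 cutoff is meaningful only relative to a trained
model's output scale.  PD-L1 enters analyses as a covariate; assay
details, iRECIST adjudication and pseudo-progression review are out of
scope.  Acquisition harmonization beyond SUV conversion and voxel-size
matching is not attempted.
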