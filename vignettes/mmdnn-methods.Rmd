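---
title: "Multiscale patch features and multimodal deep networks for dementia staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale patch features and multimodal deep networks for dementia staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Progression towards Alzheimer's disease (AD) leaves two complementary
imaging signatures: regional gray-matter atrophy, visible in structural T1
MRI, and reduced glucose metabolism, visible in FDG-PET. This package
implements a classifier that combines both modalities at several spatial
scales to (a) separate stable from progressive mild cognitive impairment
(MCI) and (b) score any image on a continuous 0–1 staging axis from
control-like to AD-like. It consumes volumes that have already been
segmented and co-registered (ROI-labeled gray matter, metabolism images on
the same grid, and precomputed subject-to-template displacement fields);
estimating segmentations or registrations is out of scope.

## Patch parcellation

Anatomical ROIs are too coarse a unit to localize early change, and single
voxels are too noisy. The middle ground is the *patch*: each template ROI
is subdivided by k-means clustering of its voxel coordinates (physical
millimetres, so anisotropic grids are handled correctly). Instead of a
fixed number of patches per ROI, the *patch size density* is fixed: with a
nominal patch size of $s$ voxels, an ROI of $n$ voxels receives
$\max(1, \lfloor n/s + 0.5 \rfloor)$ patches, so signal is aggregated at
the same spatial scale everywhere. Three scales are used side by side
(500, 1000 and 2000 voxels per patch on clinical-resolution templates;
the desk-scale synthetic default is 40/80/160), giving a coarse-to-fine
feature hierarchy.

The k-means implementation is deliberately explicit rather than delegated:
Lloyd iterations on a k-means++-style seeding (first restart greedy
farthest-point, later restarts distance-squared sampling so restarts
explore distinct starts), ties broken towards the lowest cluster id,
empty clusters reseeded from the farthest point, ten restarts by default,
and — on problems small enough for local minima to matter (at most 512
points) — a Hartigan-style single-point exchange pass between Lloyd runs.
The exchange step uses the exact SSE delta for moving one point, so the
final state is simultaneously Lloyd-stable and single-move-stable; on
instances of up to eight points it reproduces the exhaustive-partition
optimum, which the test suite checks against a brute-force oracle.

Patch maps are transferred to each subject through a displacement field
with the pull-back convention (subject voxel centre + vector = template
coordinate) and nearest-neighbour lookup, since labels are categorical.
Nearest-neighbour ties round half-up: symmetric contractions place mapped
coordinates exactly on half-voxel boundaries, and half-even rounding
would push both boundary ties outward, biasing transferred volumes low.
Patches emptied by a deformation stay in the table with zero voxels and
are flagged for imputation.

## Features

Two features per patch: its subject-space **volume** (voxel count times
voxel volume; the deformation encodes local expansion and contraction, so
this measures structure) and its **mean metabolism** after dividing the
PET image by its mean intensity over the brainstem, a reference region
presumed unaffected by AD. Brainstem normalization makes metabolism
features invariant to global scanner scaling; the package takes the
brainstem as a designated label of the ROI volume. Missing (empty-patch)
entries impute to 0 for volume — a vanished patch genuinely has no volume
— and to the training-column mean for metabolism, where zero would be a
fabricated signal; every imputation is logged.

Features are standardized to mean 0, population SD 1 using training-set
statistics only. The underlying method description is silent on feature
scaling; standardization is the package default because raw patch volumes
span orders of magnitude across scales and destabilize ReLU autoencoder
training, and it can be disabled (`train_config(standardize = FALSE)`)
to run the unscaled reading.

## The network

Each of the six (modality × scale) feature sets feeds one branch DNN;
every DNN — branches and fusion alike — has three hidden ReLU layers of
widths $3N$, $\mathrm{round}(3N/4)$ and $100$, where $N$ is its input
dimension, followed by a two-class softmax. Training proceeds in three
stages:

* **Stage A.** Each branch is pretrained greedily as a stacked
  tied-weight autoencoder ($y = \mathrm{relu}(W_1 x + b_1)$,
  $z = \mathrm{relu}(W_1^\top y + b_2)$, squared-error loss
  $\tfrac12\lVert x - z\rVert^2$), each layer reconstructing the previous
  layer's codes. A zero-initialized softmax head is then trained with the
  encoders frozen, and finally the whole branch is fine-tuned as an MLP
  under the mean cross-entropy loss.
* **Stage B.** The six 100-d penultimate-layer codes are concatenated
  (600-d) and a fusion DNN of the same design is pretrained, head-trained
  and fine-tuned on them.
* **Stage C.** All branch-encoder and fusion parameters are tuned jointly
  end-to-end through the concatenation. Gradients flow from the fusion
  softmax only; the branch heads are stage-A artefacts that no longer
  update (the method description leaves their role in joint tuning open,
  and excluding them keeps stage C a single well-defined objective).

Optimization is Adam (default learning rate $10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on mini-batches of 50 samples,
reshuffled every epoch, with a trailing smaller batch used as-is.
Inverted dropout with rate 0.5 follows every hidden layer during
supervised training — survivors are scaled by $1/(1-p)$ so that eval
mode, where all units are kept, matches the training expectation — and is
off during unsupervised pretraining (the description prescribes dropout
for the classifier; reconstruction pretraining is run undistorted).
Supervised phases stop early once validation accuracy has not strictly
improved for `patience` epochs (default 50), restoring the parameters of
the best epoch, earliest in case of ties. Pretraining and head-only
training run a fixed number of epochs. Given a seed, every stage is
bit-reproducible; analytic gradients of both losses are verified against
central finite differences in the tests.

Probability clipping at $10^{-12}$ guards the cross-entropy logarithm.
The positive-class softmax output is the per-network *staging score*:
0 reads as most control-like, 1 as most AD-like.

## Ensembles and experiment designs

Small validation sets make early stopping noisy, so classification uses a
voting ensemble: the training subjects are divided into ten disjoint
sets; network $i$ validates on set $i$ and trains on the other nine. At
test time the ten probability pairs are summed and the larger sum wins;
an exact tie goes to the negative class (a deterministic, conservative
choice for a screening context). The ensemble staging score is the summed
positive probability divided by the member count.

Two validation designs mirror the clinical questions. *Stable vs
progressive MCI*: one image per subject (baseline for sMCI; for pMCI the
earliest image within three years before conversion, falling back to the
image closest to conversion), 10-fold cross-validation allocated at the
subject level. *Controls vs dementia-positive*: sNC images against a
positive class enriched in three steps (sAD; +pMCI; +pNC), subject-level
folds over the trained groups; progressive groups excluded from a given
training level are scored in every fold and their metrics averaged over
folds (the aggregation is not specified upstream; averaging keeps every
fold's estimate on equal footing). All images of a training subject train;
all images of a test subject test. Accuracy, sensitivity (correct
positives) and specificity (correct sNC) are reported as mean ± SD over
folds plus pooled counts, and accuracy can be binned by years to
conversion: bin $y$ covers $(y-1, y]$ years before conversion, bin 0 the
images at or after conversion.

## The synthetic cohort

Real cohort data sit behind access control, so the package ships a
generator that emulates the study's structure without any download. Five
groups (default 30 sNC, 30 sMCI, 12 pNC, 30 pMCI, 30 sAD — progressive
controls are rare clinically, hence the smaller group) carry a latent
stage in $[0,1]$: 0 for sNC, a floor of 0.1 for sMCI (diagnosed
impairment without known progression), 1 for sAD, and
$\mathrm{clamp}(1 - \text{years}/\tau,\, 0.1,\, 1)$ for progressive
subjects with $\tau = 8$ years, the horizon over which conversions are
observed. Baseline years-to-conversion draw uniformly from the upper half
of $(0.5, 8)$ for pNC and the lower half for pMCI — progressive controls
are by definition farther from conversion — and longitudinal images sit
one year apart (one to two images per subject by default).

Features follow a multiplicative lognormal model, appropriate for
positive quantities: patch $j$ of image $i$ has
$\text{vol}_{ij} = \mu_j (1 - \delta_v\, \text{stage}_i\, a_j) e^{\varepsilon_{ij}}$,
$\varepsilon \sim N(0, \sigma^2)$, with affected-patch indicators $a_j$
(default 40% of patches) and the metabolism analogue $b_j$. By default
$a = b$ (atrophy and hypometabolism colocalize); the `complementary`
switch makes them disjoint to probe whether fusion preserves signal that
lives in only one modality. The fast path draws the six feature matrices
directly (default 32/16/8 patches per scale, keeping branch widths in the
low hundreds); the volumetric path builds a block-ROI template
(48³ grid, 12 ROIs plus brainstem), per-subject displacement fields that
contract affected ROIs by $1 - \delta_v \cdot \text{stage}$ per axis
about a dithered centroid, and noisy PET volumes with a group-independent
brainstem. The centroid dither (up to 2.5 voxels) plays two roles:
inter-subject anatomical variability, and spreading the scaled
coordinate lattice over a full voxel phase so nearest-neighbour counts
are unbiased across subjects instead of locked to one rounding regime.

What passing tests on this cohort do and do not show: they verify the
pipeline's mechanics — partition properties, conservation laws, gradient
correctness, leakage-free validation, learnability, null calibration, the
direction of enrichment and staging trends. They do not certify clinical
accuracy: the generator has rectangular anatomy, independent lognormal
noise, no scanner effects, no partial-volume mixing, and a linear stage
ramp, all far cleaner than real data.

## Desk-scale problem sizes and numerical choices

Experiment-level tests and the acceptance script run the full pipeline —
10-fold subject-level CV with 10-network ensembles for the MCI task,
3 folds × 3 members per enrichment level — at the synthetic defaults
above, with a training configuration scaled to those cohorts: learning
rate $10^{-3}$, 6 pretraining epochs per layer, 8 head epochs, at most
25 fine-tuning epochs with patience 7. With ~50 training images there is
one mini-batch per epoch, so the published schedule (rate $10^{-4}$,
patience 50, unbounded epochs over many batches) would apply orders of
magnitude fewer parameter updates here than in its original setting; the
desk configuration reaches the converged regime on these cohorts while
keeping a full run in minutes on one core. The package defaults in
`train_config()` remain the published values.

Other numerical choices: k-means converges on centroid movement below
$10^{-6}$ mm or a stable assignment, capped at 300 iterations;
`round_half_up` is used wherever a count is derived from a ratio (patch
counts, the $3N/4$ width); Glorot-style scaled uniform initialization for
pretrained layers and zeros for softmax heads, all drawn from the run
seed; degenerate inputs (duplicate points exceeding the distinct-point
count, empty masks, near-zero reference means, constant feature columns)
raise errors or map to defined values rather than propagating NaNs.

## Known limitations

* The artifact consumes registrations and segmentations; errors upstream
  of it are invisible to its validation.
* The printed patch totals of the original atlas (1488/705/343 at sizes
  500/1000/2000) depend on that atlas's ROI sizes and are not
  reproducible without it; the density rule, not the totals, is the
  specification.
* Longitudinal information enters only through image selection, not the
  network input.
* The staging score is a probability under a binary objective, a
  surrogate rather than a calibrated severity measure.
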