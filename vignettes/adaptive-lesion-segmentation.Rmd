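---
title: "Adaptive patch sampling for PSMA PET-CT lesion segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive patch sampling for PSMA PET-CT lesion segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Whole-body PSMA PET-CT of prostate-cancer patients contains a handful of
small hot lesions in a very large, mostly irrelevant volume. `petseg`
frames their detection as dense voxel-wise classification into four
classes — background, prostate tumour/recurrence, lymph-node metastasis,
bone metastasis — by a compact 3D U-Net over three co-registered inputs:

* the CT volume, clamped to [−800, 800] HU,
* the PET volume in SUV, clamped to [0, 25],
* a multi-channel binary organ mask (here: prostate bed, pelvic nodes
  region, skeleton, soft tissue) that gives the network anatomical context
  it could not infer from intensities alone.

"Normalised" is implemented as the affine map of each clamp window onto
[0, 1]; zero-centred variants would be an equally defensible convention,
but the unit interval keeps the organ channels, CT and PET on one scale and
makes channel validation trivial (`stackInputChannels()` rejects values
outside [0, 1]). All volumes are resampled to a common
1.37 × 1.37 × 2.79 mm grid — trilinear for continuous images, nearest
neighbour for organ masks and labels so no new class codes can appear; the
output shape per axis is the physical extent over the target spacing,
rounded half-up, so grid shapes are reproducible.

The classifier itself is deliberately architecture-light: `encoderDepth`
resolution levels (default 2) of one 3×3×3 convolution + ReLU + 2×2×2 max
pooling, a bottleneck convolution, nearest-neighbour upsampling with skip
concatenation, and a final 1×1×1 convolution with softmax. Exactly two
dropout sites (rate 0.25) sit at the deepest encoder/decoder junctions, and
all convolution weights carry an L2 penalty of 0.001. Every building block
— im2col+GEMM convolution, pooling with argmax bookkeeping, backprop, the
Nadam (Nesterov-accelerated Adam) optimiser — is implemented in the package
(RcppArmadillo for the convolution core), because no deep-learning
framework is part of this package's dependency set; the backward pass is
verified against central finite differences in the test suite to a relative
error below 1e−5.

## Loss-adaptive patch sampling

Patches (default 64×64×32 voxels; all sizes must divide by
2^`encoderDepth`) are drawn *per voxel*: each training study carries a
sample mask `w_p ≥ 0`, a categorical distribution over voxels from which
patch centres are drawn. "Foreground patch" means the centre voxel is
foreground.

* **Initialisation** puts half the total weight uniformly on background
  voxels and splits the other half equally among the foreground classes
  *present* in the study, uniformly within each class. A study with no
  foreground falls back to a uniform mask, so every study stays usable.
* **Adaptation.** After each training round, half of the training studies
  are selected at random and their masks are updated from the per-voxel
  loss `l_p` of the current model:

  `w_p' = 0.5 · w_p + 0.5 · (max_P w / max_P l) · l_p`

  so the highest-loss voxel gains a contribution equal to the current
  maximum weight. The update is covariant under uniform rescaling of `w`
  (both terms scale linearly with `max_P w`), so it is immaterial whether
  it is applied to raw or sum-normalised weights — the package stores masks
  normalised to sum 1 and re-normalises after each update, and a test
  asserts the covariance. Two degenerate cases are fixed by continuity: an
  all-zero loss map leaves the mask unchanged (no hard examples), and a
  spatially constant loss makes the uniform mask an exact fixed point.
* **Validation masks are frozen** at initialisation and never
  loss-refreshed: validation must not adapt to the model it is judging.

Patches at the volume edge are mirror-padded (reflection without edge
repeat), avoiding the constant-value artefacts of zero padding.

## Training regime

Weighted categorical cross-entropy, `−w_c log p`, with `w_c = 2.5` for the
three lesion classes and 1 for background, trades precision for
sensitivity — in screening-style use a missed lesion is costlier than a
false positive that a physician can discard. Probabilities below 1e−7 are
clamped before the log and the clamping is logged. The scalar loss is the
mean over patch voxels.

The full-scale regime is 5 rounds × 10 epochs, 20,000 training and 10,000
validation patches per epoch, initial learning rate 0.001 halved when the
validation loss has not decreased for 5 epochs, batch size 8, with one
mask refresh after every round. Whether those 10 epochs were meant per
refresh round or in total is genuinely ambiguous in this family of
training schedules; the package makes it configurable and defaults to
10 per round.

Augmentation draws one isotropic scale from ±10%, one in-plane rotation
from ±0.15 rad and per-modality intensity shifts: ±0.5 **SUV** for PET and
±100 HU for CT. Both shift ranges are read in raw image units and applied
as the equivalent shift on the normalised channels: the CT range is
conventionally quoted in HU, and reading the PET figure in normalised
units would mean ±12.5 SUV — more than most lesions' contrast — so the
SUV reading is adopted and recorded here as a deliberate design decision.
Geometric transforms use trilinear interpolation for CT/PET and nearest
neighbour for organ channels and labels.

## Inference, evaluation and burden

Whole-volume prediction is not part of the patch-training contract, so the
package defines it explicitly: sliding-window tiles (default 32×32×16,
overlap 8×8×4), per-voxel probabilities averaged over overlapping tiles,
dropout disabled, argmax with ties broken toward the lower class code —
every choice made for determinism. Volumes smaller than one tile are
mirror-padded and cropped back.

A *lesion* is a maximal 26-connected component of one class — the most
permissive standard connectivity, producing the fewest split lesions; the
evaluation is class-specific (a node candidate cannot match a bone
reference). Matching uses *any* voxel overlap: a reference lesion with at
least one overlapping same-class candidate voxel is detected, a candidate
with at least one overlapping reference voxel is a true positive. Detected
references and TP candidates are tracked separately so one candidate
spanning two references raises sensitivity without inflating PPV. This
yields the exact duality FP(X vs Y) = FN(Y vs X), which the tests verify
against a brute-force voxel-overlap oracle on a thousand random lesion-set
pairs. In pooled report tables, summary rows across references are averages
of per-reference pooled values (average-of-ratios), and studies without
reference lesions contribute FP counts but nothing to the sensitivity
denominator.

Tumour burden per class: TLV is voxel count × voxel volume in mL; TLU is
SUVmean × TLV per lesion, summed over lesions (SUV·mL) — the standard
total-lesion-uptake construction analogous to total lesion glycolysis;
adding an SUV to a volume would be dimensionally meaningless, so this
reading is adopted deliberately. Burden agreement between readers is
summarised by Spearman rank correlation with average ranks for ties.

## The phantom: what it does and does not emulate

Clinical PET-CT cannot ship with a package, so the `phantom` module
generates studies with known truth: an ellipsoidal soft-tissue body with
Gaussian background uptake (mean 1.0, sd 0.15 SUV — typical soft-tissue
PSMA background), a parametric skeleton, prostate-bed and nodal
compartments mirrored in the organ mask, CT tissue levels (air −800, soft
40, bone 700 HU, sd 20), and spherical lesions of 4–8 mm radius and
4–10 SUV peak with a cumulative-normal radial profile of width 1.2 mm
approximating PET partial-volume blur. Labelled lesion voxels are
guaranteed (and asserted per study) to exceed the background mean plus one
standard deviation. *Unspecific bone foci* receive lesion-like uptake
inside the skeleton but keep the background label, reproducing the
benign-bone-uptake confound of [18F]PSMA-1007 so false-positive behaviour
is exercisable. Simulated alternative readings drop each true lesion with
probability `pDropLesion`, jitter boundaries by up to a configurable
dilation/erosion radius (erosion stops before extinction) and add spurious
small lesions with a Poisson expectation.

The phantom emulates structure, not physics: no scanner noise model, no
attenuation or reconstruction artefacts, no anatomically realistic shapes,
and lesion size/uptake distributions chosen for testability rather than
fitted to a clinical cohort. Passing tests therefore demonstrate that the
machinery — sampling, optimisation, matching, quantification — behaves as
specified, not that the classifier reaches clinical performance on real
scans.

## Determinism and problem sizes

Every stochastic stage derives its own seed from one master seed via a
string-keyed mixing function (`deriveSeed()`), so phantom generation,
sampling, dropout, augmentation, mask refresh and the reader simulation are
individually and jointly reproducible; two pipeline runs with the same
config and seed produce byte-identical CSV reports.

The test suite runs everything at reduced scale, chosen as the smallest
sizes at which each property is meaningfully exercised: 24³–48³ voxel
grids, 16³ training patches, cohorts of 4–30 studies, and an end-to-end
training of 2 rounds × 3 epochs × 200 patches. At that patch budget the
batch size is reduced to 2 — with only 600 patches in total, parameter
updates are the scarce resource, and smaller batches give the optimiser
proportionally more steps at a still-stable gradient estimate. On such
phantom cohorts the scaled-down run reaches perfect held-out lesion-level
sensitivity; the remaining false positives are dominated by the unspecific
bone foci, which is the intended behaviour of a sensitivity-biased loss
confronted with that confound.

## Known limitations

* The 3D U-Net is compact by design; filter counts and depth are
  configuration, not a tuned architecture, and no GPU path exists.
* PET is assumed to arrive in SUV; conversion from activity concentration,
  DICOM ingestion and registration are out of scope (PET-CT is acquired
  co-registered).
* The organ-mask compartments are synthetic stand-ins for an external
  CT-based organ segmentation; they condition the classifier but are not
  anatomically faithful.
* Lesion matching counts any single-voxel overlap; no minimum-overlap
  fraction or centroid-distance criterion is offered.
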