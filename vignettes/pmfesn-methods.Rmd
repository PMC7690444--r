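---
title: "Similarity learning for ordinal stroke outcome: models, balancing, and evaluation"
author: "pmfesn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity learning for ordinal stroke outcome}
  %\VignetteEncoding{UTF-8}
---

# The problem

Predicting the three-month modified Rankin Scale (mRS, here 0–4) of an
acute ischemic stroke patient from pre-treatment imaging is a few-shot,
heavily imbalanced, *ordinal* classification problem: cohorts hold tens of
cases, one outcome grade may have only three examples, and predicting grade
4 for a grade-0 patient is a much worse error than predicting grade 1. The
input per case is six co-registered, skull-stripped 3D parameter maps:
apparent diffusion coefficient (ADC, diffusion-derived, marking the infarct
core) and five perfusion-derived maps (MTT, TTP, Tmax, CBV, CBF, marking
salvageable tissue). Clinical covariates (time since stroke, time to
treatment, TICI grade) are parsed and carried on the `StrokeCase` objects
but never consumed by the model.

`pmfesn` treats the problem as pairwise similarity learning: instead of
classifying a case directly, a siamese network learns whether two cases
share an outcome grade, and a held-out case inherits the grade of its most
similar training case. With M classes, N cases yield O(N²) training pairs —
the central few-shot leverage.

# Preprocessing

Volumes arrive at arbitrary per-case resolution and are resized to a
common working grid, 150 × 150 × 21 by default (`resizeVolume`). Resizing
is separable linear interpolation with endpoint alignment: the first and
last samples of each axis map exactly onto the first and last output
samples, so constant volumes stay constant and linear ramps stay linear
with preserved endpoints. No intensity standardization or bias-field
correction is applied — ADC and perfusion maps do not require it.

The network consumes only the three middle axial slices per modality,
stacked as channels (`extractMiddleSlices`): for depth D these are the
0-based indices ⌊D/2⌋−1, ⌊D/2⌋, ⌊D/2⌋+1 — the unique symmetric triple for
odd D (9, 10, 11 at D = 21). Whole-volume input is a known extension, not
implemented here.

Within every evaluation fold, the voxelwise per-modality *mean image* of
the training samples — originals and augmented alike, since both are
training data in the fold — is subtracted from all training slabs and from
the held-out slab (`foldMeanCenter`). Whether "the training mean" denotes
an image or a scalar is genuinely open; the mean image is the more natural
reading and is the package's convention.

# Stage-1 balancing: augmentation

`augmentToBalance` raises every class to the size `I` of the largest class
by generating `I − n_m` new samples from random geometric transforms: zoom,
rotation, translation, shear, horizontal and vertical flip. The transform
families are fixed by the method; the magnitudes are package defaults
(rotation ±10°, zoom 0.9–1.1, translation ±10 %, shear ±0.1, both flips
allowed), configurable through `AugmentationPolicy`. Three conventions
matter:

* One transform per new sample, applied *identically* to all six modality
  slabs — augmentation must not break co-registration. Each augmented
  sample stores its transform, and reapplying it to the source slabs
  reproduces the augmented slabs bit-exactly (a tested invariant).
* Transforms act in-plane on the prepared H × W × 3 slabs (the object the
  network actually consumes), not on the raw 3D volumes; whether to warp
  volumes or slabs is unstated in the underlying method and slab-level
  warping is the package's choice.
* Out-of-border pixels are filled with 0, consistent with skull-stripped
  background. Pure flips land exactly on the mirrored grid and are
  bit-exact; the general warp is inverse-mapped bilinear interpolation
  about the slab center.

Source originals for the new samples are cycled round-robin in a seeded
random order. Only training data pass through this stage; the held-out
case of a fold is never augmented, and augmented samples never enter the
test-time reference set.

# Stage-2 balancing: pair construction

From a balanced training set, `buildPairs` creates

* **SP**: every unordered within-class pair, label 1 —
  `S = Σ_m C(n_m, 2)` pairs in total;
* **DP**: for each of the `Z = C(M, 2)` unordered label pairs, exactly
  `⌊S/Z⌋` distinct cross-class pairs sampled uniformly without
  replacement, label 0.

Equal allocation across label pairs is the point: plain random sampling of
S dissimilar pairs would over-represent the label pairs of large classes.
When Z does not divide S the allocation is floored, accepting |DP|
slightly below |SP| in exchange for exact equality across label pairs; when
⌊S/Z⌋ = 0 (toy-sized sets never reached by the method's own cohorts) the
package warns and proceeds with an empty DP rather than inventing an
intent. `splitTrainVal` then makes a 7:3 train/validation split,
stratified by pair label via floor plus largest-remainder so the overall
total is round(0.7 n) exactly.

# The model

Six branch CNNs — one per modality, weights *not* shared across modalities
— each embed a slab into 10 dimensions; concatenation in canonical modality
order gives a 60-dimensional embedding. The two samples of a pair pass
through the same branches (twin sharing), which makes the pair score
symmetric in its arguments bit-for-bit and halves the parameter count.

The fidelity backbone is VGG16 up to convolutional block 5 (13 conv layers;
at 150 × 150 × 3 input the pooling ladder is 150→75→37→18→9→4, flatten
8192), followed by batch normalization, dense(20, ReLU) and dense(10,
ReLU). Blocks 1–4 are frozen; block 5 and the head are fine-tuned. One
branch holds 14,911,526 parameters, 7,259,878 of them trainable
(block-5 convs 3 × 2,359,808, batch-norm scale/shift 2 × 8192, dense
163,860 + 210); batch-norm moving statistics are counted non-trainable.
These counts are reproduced exactly by `branchSpec("vgg16")` /
`countParameters` and asserted in the tests. In the fidelity setting the
conv filters would be transplanted from pretrained weights; the package
initializes them randomly so that construction, counting and training work
fully offline — pretrained initialization is an external artifact, not part
of the method's logic.

The `toy` backbone keeps the identical head and freeze policy (all conv
blocks but the last frozen) over a configurable ladder of single-conv
blocks; it exists so the full pipeline can be *trained* at desk scale and
is first-class, tested code.

The pair score is `sim(u, v) = (1 + cos(u, v)) / 2` with
`cos = u·v/(‖u‖‖v‖ + 1e-8)`. The underlying method says only that the
cosine is normalized into [0, 1]; with ReLU embeddings the cosine is
non-negative anyway, but (1 + cos)/2 is total and symmetric, and a
zero-norm embedding yields cosine 0, hence similarity 0.5. Binary
cross-entropy on the pair label is minimized by SGD with learning rate
1e-4, momentum 0.9, batch size 32, at most 20 epochs. Non-convolutional
weights start from N(0, 0.01); randomly initialized conv filters use
N(0, 0.05) (batch normalization makes the head insensitive to this scale);
batch-norm uses ε = 1e-3 and a 0.9 moving-average momentum for its
statistics. Pairs are reshuffled before every epoch; within a mini-batch
each unique sample is embedded once per modality (training-mode batch
statistics) and the loss gradient accumulates through the shared weights.

Early stopping watches the *training* loss: the first epoch whose
improvement is ≤ 1e-4 arms the stop, and training halts after `patience`
(default 1) further epochs — an improvement of 5e-5 at epoch 3 halts
training at epoch 4. The 7:3 validation loss is recorded per epoch
(inference mode) but only monitored. The entire engine — conv/pool kernels
in compiled code, batch-norm/dense/head in R — is validated against central
finite differences layer by layer.

# Inference and the evaluation harness

`predictCase` pairs the held-out sample with every *original* training
sample (provenance-checked; augmented samples are rejected), takes the
class of the argmax similarity, breaks exact ties uniformly at random (tie
flagged), and records per-class scores as the max similarity over each
class's originals. `locoEvaluate` runs the whole pipeline from scratch
inside every leave-one-case-out fold — augmentation, centering, pairing,
splitting, training, prediction all see only the remaining cases — and
aggregates the folds into an `EvaluationReport`. A fold whose held-out
class retains no training exemplar still runs (it can only miss; the fold
is flagged `structural_miss`), which only arises for single-case classes.
All per-fold randomness derives from the run seed, so identical seeds
reproduce the report bit-for-bit on a fixed platform.

# Metrics

All reported metrics weight classes equally, regardless of size:

* **MAE^M**: the within-class mean absolute deviation |y − ŷ|, averaged
  over classes; range [0, M−1]. Classes absent from the truth vector are
  dropped from the average with a warning (their within-class mean is
  undefined). For continuous regressor baselines the predictions may be
  left unrounded.
* **Macro P/R/F1**: P_m = diag/colsum, R_m = diag/rowsum with 0/0 → 0
  (a never-predicted class has precision 0); Pmacro/Rmacro are unweighted
  means, and F1macro is the harmonic mean *of the macro averages* — not
  the mean of per-class F1. The two definitions differ, and only this one
  is consistent with the summary values the package's tests pin down.
  Per-class "accuracy" under this scheme equals per-class recall.
* **MCC** (Gorodkin's multiclass form) from the confusion matrix's trace
  and marginals, 0 when a radicand vanishes; it coincides with the
  classical binary MCC on 2 × 2 tables (tested equivalence).
* **Per-class AUC**: one-vs-rest rank-based (Mann–Whitney) AUC with ties
  counted ½, on the per-class max-similarity scores. How to score a
  discrete nearest-neighbour classifier for ROC purposes is not dictated
  by the method; max similarity per class is the package's interpretation.
  A class lacking either positives or negatives reports NA.

# The synthetic data generator

`generateDataset` emulates the *structure* of a multi-parametric stroke
cohort so every stage is exercisable without restricted data: per case,
six volumes share one lesion geometry (the synthetic analogue of
co-registration) — an ellipsoid with random center and semi-axes, smooth
falloff toward the rim — plus per-modality baselines, fixed per-modality
contrast factors (negative for ADC/CBV/CBF, which drop in lesions;
positive for the timing maps, which rise), and i.i.d. Gaussian noise. Both
the lesion amplitude, `effect_size × (1 + label)`, and its extent grow
with the ordinal label, so nearby grades genuinely look more alike than
distant ones and MAE^M is meaningful. `effect_size = 0` removes all class
information; equal configurations are bit-reproducible.
`separabilityCheck` (leave-one-out nearest-centroid on per-modality mean
intensities) is the generator's independent sanity oracle: near chance at
zero effect, near perfect when the signal dwarfs the noise.

What the generator does **not** emulate: brain anatomy, real perfusion
physics, scanner/site effects, registration error, or multi-focal lesions.
Passing the pipeline tests on synthetic cohorts therefore demonstrates
that the machinery is correct and that the method recovers a
label-monotone signal under heavy imbalance — not that any particular
clinical accuracy would be attained on real data.

# Problem sizes and numerical choices

The package's own evaluation runs use desk-scale study conditions chosen
once: synthetic cohorts of 43 cases with per-class counts (4, 18, 11, 7,
3) — matching the heavy imbalance and 3-case minority of the motivating
cohort — volumes 16 × 16 × 9, preprocessing target 8 × 8 × 9 (slabs
8 × 8 × 3), toy backbone with 6/12 filters and the first block frozen,
lesion effect five times the noise, five seeds. At this scale a full
five-seed LOCO sweep trains 215 networks in a few minutes on one CPU while
macro recall stays far above the 0.2 chance level; the 150 × 150 VGG16
configuration remains available for fidelity work but is not trained by
the tests.

Remaining numerical conventions: BCE probabilities are clamped to
[1e-7, 1 − 1e-7]; cosine uses ε = 1e-8 (so self-similarity is 1 up to
~1e-6 for small-norm embeddings); pooling floors odd dimensions (dropping
the trailing row/column, as in the VGG16 ladder); exact similarity ties at
prediction time are resolved by a seeded uniform draw.

# Known limitations

* Training the VGG16 backbone at full scale is impractical on one CPU;
  the toy backbone carries all trained tests.
* Pretrained conv initialization (the fidelity setting) is supported
  structurally but not shipped; random conv initialization changes where
  fine-tuning starts, so desk-scale results characterize the pipeline, not
  transfer learning.
* Bit-exact reproducibility holds for a fixed BLAS/platform; across
  platforms, losses agree only to floating-point reassociation.
* The ordinal structure of mRS enters through the evaluation (MAE^M) and
  the synthetic generator, not through the loss: pair labels are binary,
  as the method defines them.
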