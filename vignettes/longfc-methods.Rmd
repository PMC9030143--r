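---
title: "LongFC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LongFC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Alzheimer's disease (AD) degrades the brain's functional networks
progressively. Resting-state fMRI summarizes those networks as a
functional-connectivity (FC) matrix: with the brain parcelled into R atlas
regions and each region's voxel signals averaged into one time series, entry
(i, j) is the Pearson correlation

$$\rho_{X,Y} = \frac{\mathrm{Cov}(X, Y)}{\sigma_X \sigma_Y}$$

between the series of regions i and j. A single scan gives one such matrix;
a longitudinal design observes each subject at baseline (BL), 12 months and
24 months, so disease progression appears as a trajectory of FC matrices.
LongFC implements a classifier built for exactly that structure — a
per-timepoint convolutional feature extractor whose weights are shared
across timepoints, fused across the scan sequence by a stacked LSTM — for
two binary tasks: separating normal controls from AD (NC-vs-AD), and
predicting which mild-cognitive-impairment patients will convert
(sMCI-vs-pMCI, the clinically important case). The package covers the full
path from ROI time series (or 4D image + atlas) to cross-validated metrics,
including a synthetic-cohort simulator so every stage is testable without
access-restricted clinical data.

## Connectome construction and quality control

`extractRoiTimeseries()` averages, frame by frame, the voxels of each atlas
label; the first `dropLeading` frames (default 10, matching the convention
of discarding pre-steady-state volumes from a 140-frame acquisition) are
removed first. `pearsonFC()` computes the correlation matrix using
population (divide-by-T) moments — the convention cancels in the ratio, but
it is stated here for anyone comparing intermediate covariances. Three
numerical policies matter:

* the diagonal is **assigned** 1, never computed, avoiding 0/0 on constant
  signals;
* a zero-variance region's correlations are set to 0 with a warning rather
  than propagating NaN (degenerate signals are a data problem the user must
  hear about, but they should not crash a batch);
* off-diagonal values are clamped to [-1, 1] after floating-point rounding,
  and symmetry is enforced exactly, so every `FCMatrix` satisfies its
  validity invariants bit-for-bit.

Motion quality control follows the framewise-displacement rule
`fdExclude()`: count frames with FD strictly above 0.5 mm and exclude the
subject when strictly more than 50 such frames occur (2.5 minutes of data
at a 3 s TR). Both boundaries are read strictly — a frame at exactly the
threshold, or exactly 50 bad frames, keeps the subject — and both numbers
are parameters, because the strictness convention is a choice, not a fact.
Correlations are fed to the models raw: no Fisher z-transform and no
thresholding, keeping the per-timepoint input exactly the FC matrix.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` draws every subject-timepoint series from a zero-mean
multivariate normal whose covariance is a (group, timepoint)-specific
correlation template. Under a Gaussian model, the Pearson FC matrix fully
characterizes the dependence structure, so the templates are precisely the
quantity the pipeline estimates — the simulator and the estimator meet in
the middle, which is what makes the null and signal-recovery experiments
clean.

Templates (`buildTemplates()`) start from one base correlation matrix built
by randomly orthogonally mixing independent factors with geometrically
decaying variances (ratio about 20 between the largest and smallest), then
normalizing to unit diagonal; this yields off-diagonal correlations of
realistic magnitude rather than the near-zero entries a white-noise
construction would give. Disease is modelled as *connectivity loss*: a
fixed random subset of `affectedEdgeFraction` of the R(R-1)/2 edges is
shrunk toward zero by a factor `edgeEffect` in non-NC groups, with an extra
`t * progressionRate` shrinkage at follow-up timepoint index t for the
progressive groups (pMCI, AD). sMCI carries the static deficit but does not
progress; NC is stable. The affected-edge subset is fixed per cohort — not
per subject — so the group signal is learnable. Between-subject
heterogeneity enters as correlation jitter of scale `subjectNoiseSd` on the
subject's template, re-projected to a valid correlation matrix (eigenvalue
clipping and diagonal re-normalization) before sampling.

Defaults are the desk-scale study the test-suite experiments use: R = 20
regions, T = 130 frames (140-frame scans minus 10 dropped leading volumes),
50 subjects per group, `edgeEffect` 0.5 on 30% of edges,
`progressionRate` 0.15, `subjectNoiseSd` 0.05. The effect magnitudes are
calibration knobs chosen once to put the tasks in a regime where signal is
recoverable but not trivial at T = 130 (per-edge sampling noise is roughly
(1 - rho^2)/sqrt(T) ~ 0.08); they are not estimates of any clinical
cohort's true effect sizes.

The `trajectoryOnly` flag is the control experiment for the longitudinal
claim: all groups share the baseline template, and the progressive groups
carry the full `edgeEffect` at the 12m and 24m scans. Each follow-up scan
is then exactly as discriminable as in the static design, the baseline is
pure chance for any classifier, and the group difference lives entirely in
the trajectory. A baseline-only model faces chance; a single-follow-up
model sees one informative scan; the sequence model can fuse two — which
isolates the value of longitudinal fusion. (Two ramped variants of this
control — divergence growing linearly over the follow-ups — were evaluated
and discarded: they starve the follow-up scans of signal at desk-scale
sample sizes, so every method degenerates toward chance and the comparison
measures noise rather than fusion.)

What the simulator deliberately does not emulate: BOLD temporal
autocorrelation (the pipeline treats frames exchangeably, and Pearson
correlation is invariant to it in expectation), scanner artifacts, head
motion (FD traces for QC tests are synthesized directly), site effects, and
non-Gaussian tails. Passing tests on this cohort therefore demonstrate that
the machinery recovers the kind of structure it assumes, not that it will
reach any particular accuracy on clinical data.

## The classifier

Each FC matrix enters as the vectorized strict upper triangle, row-major —
R(R-1)/2 = 190 values at R = 20 (4005 at R = 90) — since the lower triangle
and unit diagonal carry no information. Edge vectors are standardized
per edge with training-set statistics before the network (standard neural
practice; the statistics travel with the model).

**Residual 1D-CNN.** The extractor applies three blocks of same-padded
1D convolution (channels 16/32/64, kernel 5), ReLU, and max-pooling
(width 2, floor truncation), with exactly two short-connection modules:
block 1's output is pooled and 1x1-projected onto block 3's input, and
block 2's output likewise onto the final feature map, fusing front-layer
with rear-layer features. Shortcut shape consistency is checked at build
time; a mismatched configuration never reaches the forward pass. The final
feature map is flattened (positions x channels) and mapped linearly to a
64-dimensional embedding. Flattening rather than global average pooling is
a considered choice: averaging across positions makes the extractor nearly
translation-invariant along the edge axis, but edge *identity* is the
signal in a connectivity vector — there is nothing translation-invariant
about which pair of brain regions an entry connects. In development the
global-average variant left substantial held-out accuracy on the table on
cohorts a linear SVM separates perfectly, while the flattened variant
recovers the signal; `cnnConfig(pooling = "gap")` retains the other
behaviour.

**LSTM fusion.** The three embeddings (BL, 12m, 24m), produced by the
*same* CNN parameters and bounded to (-1, 1) by a tanh on the embedding
map (so they sit in the recurrent cells' linear range), feed a three-layer
LSTM (hidden size 64 per layer, dropout 0.2 between layers with masks
shared across timesteps). Each cell
applies the standard gates: forget f = sigma(W_f [h, x] + b_f), input
i = sigma(W_i [h, x] + b_i), candidate c~ = tanh(W_c [h, x] + b_c), cell
state c = f * c_prev + i * c~, output o = sigma(W_o [h, x] + b_o), hidden
h = o * tanh(c). The forget-gate bias is initialized at 1 so cells start by
retaining state. The top layer's final hidden state passes through a linear
map and sigmoid to one probability; the decision threshold is 0.5, and the
positive class is the more-diseased label (AD; pMCI), so recall reads as
sensitivity to disease. Truncated scopes unroll the same stack over 1 (BL)
or 2 (12m) steps, which is how the comparison table gets all timepoint
rows. Missing timepoints are an error, never imputed.

**Training.** Binary cross-entropy, Adam (learning rate 1e-3, batch 16,
up to 200 epochs), with a seed-controlled 20% validation split of the
training data and the best-validation-loss epoch checkpointed. Training is
two-stage, the standard scheme for CNN+RNN longitudinal models: the shared
extractor is first trained with a direct per-scan head, every timepoint
carrying its subject's label (`pretrainEpochs`, default 30), and the full
sequence model then trains from that initialization, by default with the
extractor frozen (`freezeCnn`). The stage matters: a three-layer recurrent
stack between the extractor and the loss gives the extractor a weak,
easily-memorized learning signal on small cohorts — in our experiments
single-stage training could leave validation loss at chance while training
loss went to zero, with the identical extractor generalizing well when
supervised directly. When pretraining is on, the stack itself starts
recency-dominant rather than random: candidate gates pass their input
through coordinate-wise, forget gates are biased toward forgetting, input
and output gates toward open, and the head is initialized from the
pretrained per-scan read-out — so the initial sequence model approximately
applies the per-scan classifier to the latest scan, and training then
learns how much history to keep. On small cohorts this initialization is
the difference between reliable fine-tuning and seed-dependent collapse.
Optional decoupled weight decay (`weightDecay`) is available but defaults
to 0. All
forward/backward passes are hand-written vectorized R (no tensor library is
involved); the analytic gradients of the fully composed model are verified
against central finite differences to 1e-4 relative error in the test
suite. Training is a deterministic function of the data and the seed —
initialization, shuffling, the validation split and dropout all draw from
the seeded generator.

## GAN augmentation

`trainGAN()` trains, per class, a small generator/discriminator pair on the
edge vectors: the generator maps gaussian noise through a ReLU MLP with a
tanh output (edge correlations live in [-1, 1]); the discriminator mirrors
it with a sigmoid head; losses are the standard non-saturating pair; both
networks use Adam with beta1 = 0.5 (the usual GAN setting — momentum 0.9
destabilizes the minimax updates). Generated vectors are rebuilt into full
matrices and pushed through `projectToValidFC()` — symmetrize, clip,
unit diagonal — so every synthetic sample satisfies the FC invariants by
construction. Positive semi-definiteness is deliberately not enforced: the
classifier consumes raw matrices, and projecting to the PSD cone would
distort the edge distribution the GAN was trained to match.

`augmentSamples()` builds synthetic longitudinal subjects by training one
generator per (class, timepoint) cell and assembling the i-th draws into a
subject. Within-subject correlation across timepoints is consequently not
modelled in synthetic subjects — they augment the marginal per-timepoint
class distributions. This is a known limitation; the evaluation harness
measures its cost directly (augmentation must not reduce pooled accuracy
materially), and all generators are fit strictly inside the training fold,
with `synth-` subject-id prefixes so fold hygiene is auditable.

## Evaluation design

`kfoldSplit()` assigns whole subjects to five folds, stratified by class
within one subject; all of a subject's timepoints stay together, so no
test scan's sibling ever leaks into training. `computeMetrics()` implements
accuracy = (TP+TN)/(TP+TN+FN+FP), precision = TP/(TP+FP), recall =
TP/(TP+FN), each also as a percentage; an undefined metric (zero
denominator) is NA with a warning, never silently 0. `rocAuc()` sweeps the
distinct scores as thresholds (ties grouped) and integrates by trapezoid,
which equals the Mann-Whitney pair-counting statistic with ties counted
half. Headline numbers are pooled (micro) metrics — confusion counts summed
over the five test folds — with per-fold mean and sd alongside.

`runComparison()` mirrors the three-way method comparison: a linear-kernel
SVM (cost 1) on the same edge vectors and a CNN-only model (the identical
extractor with the head applied directly, no recurrence) each consume a
single timepoint, while CNN+LSTM consumes the sequence up to the scope
timepoint. Scope `"all"` evaluates the single-timepoint methods at each
timepoint separately. When the longitudinal model is compared against
"single-timepoint CNN" as a class of analysis, we average the CNN-only
accuracy over the three timepoints: a practitioner restricted to one scan
has no principled way to know which timepoint will discriminate best, so
the average — not the best timepoint in hindsight — is the fair comparator.

Two cautions on interpretation. On the default (static-effect) Gaussian
cohort the optimal decision boundary is nearly linear, so the SVM baseline
is extremely strong there — sometimes perfect; the neural models' advantage
appears on the trajectory-only cohorts, where the discriminating structure
is longitudinal. And none of the synthetic-cohort accuracies transfer to
clinical data; the experiments establish correctness and ordering
properties, not clinical performance.

## Pipeline and reproducibility

`runPipeline()` executes simulate -> FC -> evaluate -> report from one
nested config (YAML/JSON; unknown keys are rejected before any stage runs).
A single global seed derives per-stage seeds by hashing the stage name, so
any stage can be reproduced in isolation; every run directory carries the
full config, its MD5 hash, the fold assignment, per-epoch loss curves of a
final sequence model, ROC points per method, and a structured log.
Identical configs produce byte-identical metrics tables. Numbers in
metrics files are written at fixed 10-digit precision for that purpose;
logs carry timestamps, metrics files never do.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run the desk-scale designs: unit
tests use 5-10 subjects per group at R = 6-10; the statistical experiments
use the default R = 20, T = 130 cohorts with 50-100 subjects per group, a
reduced network (channels 8/16/32, embedding 32, hidden 32, batch 32,
40-60 epochs with best-epoch checkpointing) — sized so each experiment is a
few minutes of single-core compute while keeping every accuracy well away
from its decision boundary. The full-size defaults (channels 16/32/64,
hidden 64, 200 epochs) behave equivalently but slower; both are pure
config.

## Known limitations

* The simulator's Gaussian, temporally-white generative model understates
  the difficulty of real rs-fMRI (autocorrelation, motion, site effects).
* Synthetic augmented subjects have independent timepoints.
* The SVM baseline uses a fixed cost (1.0) without tuning, as a reference
  point rather than a tuned competitor.
* Sequences shorter than three timepoints are supported only through the
  BL/12m truncated scopes; arbitrary missingness is out of scope.
* The NIfTI path assumes the atlas is already aligned voxel-for-voxel with
  the image; no registration is performed.
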