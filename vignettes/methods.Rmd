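---
title: "Multiphase DCE-MRI invasion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase DCE-MRI invasion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Distinguishing non-muscle-invasive from muscle-invasive bladder cancer
(NMIBC vs. MIBC) on dynamic contrast-enhanced MRI is hard precisely in the
cases where radiologist scoring is ambiguous. The discriminative information
is spatiotemporal: how the tumor and the adjacent bladder wall enhance over
the acquisition phases (wash-in and washout kinetics), and whether enhancing
tumor tissue extends into the muscular wall layer. `windmri` implements a
classifier built around that idea: a multiscale 3D convolutional token
extractor over the phase stack, a windowed transformer attention module that
fuses local temporal context, and a sigmoid classification head — together
with the evaluation statistics and saliency tooling a study of such a
classifier needs, and a synthetic phantom generator so the entire pipeline
runs without clinical data.

# Input representation and preprocessing

One patient contributes a key-slice stack `X` of shape `H x W x T`: for each
of the `T = 5` acquisition phases (0, 30, 60, 90, 300 s post-contrast), the
2D slice with the largest in-slice tumor area is selected
(`select_key_slice()`, ties toward the lowest slice index; an empty tumor
mask is an error, not a silent default).

Z-score normalization uses a *global* mean and standard deviation pooled
over all tumor-region voxels of all phases of all **training** samples
(`fit_norm_stats()`), applied uniformly to every voxel of the cropped region
(`znormalize()`). Two details matter:

* the statistics are population moments over the pooled voxels, so the
  pooled tumor voxels standardize to exactly mean 0, variance 1;
* validation and test samples never contribute; the fitted object records
  the contributing sample ids so leakage is checkable.

The manually delineated bladder box (0-based, half-open `roi_box()`) is
cropped and resized bilinearly to the canonical `224 x 224` input
(`crop_and_resize()`; masks use nearest-neighbour so they stay binary).
Patients with a missing 60 s phase (about 5% of cases) are mapped onto the
canonical 5-phase grid by a phase projection that duplicates the acquired
phase nearest in time (`adapt_phase_count()`); a learned `1 x 1` convolution
can be substituted through the `projection` argument.

Training-time augmentation (`augment()`) composes rotation (±15°), isotropic
scaling (0.9–1.1) and translation (±10 px) into a single bilinear warp —
identical across the phases of a sample, so temporal coherence is preserved
— followed by optional Rician and Gaussian noise. Mosaic augmentation
requires four source images and is therefore exposed as a separate
`augment_mosaic()` operating on a list of four stacks; a single-image
signature cannot produce a mosaic. Class imbalance is handled by minority
oversampling; when augmentation is active, oversampled duplicates receive
independent jitter.

# The multiscale convolution token extractor

Three parallel dual-layer 3D convolution branches with cubic kernels of edge
1, 3 and 5 process the phase stack at local, medium and global receptive
fields. Each branch applies:

1. a standard 3D convolution (no bias — the following per-channel
   normalization absorbs any constant shift), channel normalization, ReLU,
   and `2 x 2 x 2` max pooling;
2. a depthwise 3D convolution with stride 2 on all axes, a `1 x 1 x 1`
   pointwise convolution, normalization, ReLU, and `2 x 2 x 1` max pooling.

The spatial side shrinks by exactly 8 (`224 -> 112 -> 56 -> 28`), forced by
the printed token feature dimension `784 = 28^2`. The phase axis collapses
along the way (`5 -> 2 -> 1`), folding temporal structure into the channels:
temporal contrasts must be — and are — expressible by the signed
phase-spanning weights of the first-layer kernels. Each output channel
becomes one token row; with the default allocation of (64, 128, 256)
channels for kernels (1, 3, 5), the concatenated output `X''` is exactly
`448 x 784` tokens. Only the total token count is externally fixed; the
per-branch allocation follows the heuristic that larger kernels carry more
context channels.

Two design decisions here deserve explanation:

* **Per-sample channel normalization.** The branches normalize each channel
  over its spatial/phase positions within the sample, with learnable gain
  and shift. A batch-statistics variant would make each sample's features
  depend on its minibatch companions, breaking seeded bit-reproducibility
  under gradient accumulation and changing behaviour between batch sizes;
  the per-sample form keeps the same parameter count and the same
  normalize-scale-shift role. Whether the second layer is normalized at all
  is a config flag (`bn_layer2`, default on).
* **Depthwise separability.** Layer 2 factorizes the dense 3D convolution
  into depthwise + pointwise; for every branch with `k > 1` the parameter
  count `k^3 c1 + c1 c2` is strictly below the dense `k^3 c1 c2`, which the
  test suite asserts numerically.

# Fused window attention

The token sequence (length `T = 448`) is split into `F = (T - W)/S + 1`
windows of `W` tokens at stride `S`; non-integral `F` is rejected loudly.
Each window sees a fringe of `L` tokens per side (edge-clamped at the
sequence boundaries) in its keys and values but not in its queries, so
adjacent windows share context without widening the output. A context/
auxiliary token — one learnable shared vector, instantiated per window —
is prepended: queries are `{c_i, x_i}` (`(1+W) x N`), keys and values are
`{c_i, a_i, x_i, b_i}` (`(1+W+2L) x N`) and share one projection, so `V = K`
literally. Scores use standard scaled dot-product attention with
`1/sqrt(d_i)` per-head scaling; a `raw_di_scaling` flag reproduces the
as-printed `1/d_i` scaling for comparison. The printed fusion rule is the
unweighted arithmetic mean of the window context outputs, followed by layer
normalization; the "weighted by importance" reading is available as a
learned-weight variant but is off by default, following the formula over the
prose.

Each transformer block is pre-norm with residual connections: windowed
multi-head attention (overlapping base-token updates are scatter-averaged
back onto the sequence), then a ReLU feed-forward. The feed-forward can be
applied to all tokens (default) or only to the context tokens — the
parameter count is identical, and the reduced form trades sequence-token
refinement for a large CPU saving in the desk-scale configurations.

Window geometry defaults to `W = 64, S = 48, L = 8` (9 windows): the stride
is below the window length so fringe fusion and overlap-averaging are
genuinely exercised, and the integrality constraint holds. None of `W, S, L`
are externally specified; all are config keys.

# Classification head, loss, and training

The fused feature maps to an invasion probability through a single affine
projection and sigmoid; NMIBC is the negative class. The loss is the mean
binary cross-entropy with probabilities clamped at `1e-7` inside the
logarithms (the loss is undefined at exact 0/1). The gradient of the
sigmoid + cross-entropy composition is the standard `p - y`, which the test
suite verifies against central finite differences along with a
finite-difference sweep over every parameter tensor of the full network.

Training uses AdamW (`lr 1e-4`, decoupled weight decay 0.01, batch 8 by
gradient accumulation, global-norm clipping at 5), per-epoch shuffling,
optional minority oversampling and augmentation, and early stopping on
validation loss (or validation AUC via `select_on`). All schedule choices
are config keys with these defaults — the source publication states none of
them. Divergence (non-finite loss) aborts with the epoch in the message
rather than continuing silently.

# Parameter budget

The default full configuration — attention depth 3, 8 heads of dimension 98,
feed-forward expansion 6 — totals 27.74 M trainable parameters, sized to the
published budget of 27.9 M (within 0.6%). With expansion 4 the same depth
lands near 20 M, which is incompatible with that budget; expansion 6 is the
smallest standard-shaped feed-forward that closes the gap at depth 3. The
parameter count is computed by summing tensor sizes at runtime
(`count_params()`), not hard-coded anywhere.

# The synthetic phantom

The generator (`simulate_cohort()`) emulates the study conditions: ~26%
invasive prevalence, five acquisitions at 0/30/60/90/300 s, Rician plus
Gaussian noise, and a 5% chance of a missing 60 s phase. Geometry is a
bladder-wall annulus around a urine-filled lumen with a half-disc tumor
seated on the inner wall; the invasive class extends enhancing tumor signal
radially into the wall annulus (85% of the wall thickness by default vs. 15%
for non-invasive). Kinetics are piecewise linear wash-in to a class-specific
peak phase followed by exponential washout; the classes share baseline
intensity and differ in wash-in slope (0.010 vs. 0.006 intensity/s), peak
timing (60 s vs. 90 s) and washout rate — mirroring the clinical claim that
*dynamics*, not static intensity, discriminate. A log-normal between-subject
spread (sd 0.25) on the wash-in slope keeps the single best temporal feature
(phase-2 minus phase-1 mean tumor intensity) at an AUC around 0.85 rather
than at ceiling, so spatial invasion cues still matter. The published
acquisition protocol gives times but no intensity curves, so these kinetics
are stipulated, not fitted — the generator demonstrates pipeline
learnability, never clinical performance. Real DCE-MRI features it does not
emulate: multi-slice anatomy, scanner-specific artifacts, pharmacokinetic
(Tofts-model) realism, and anatomical variability beyond circle/disc
geometry.

# Evaluation statistics

The invasive class is the designated positive class throughout, and every
report also prints per-class recalls so "sensitivity for NMIBC" is readable
directly — this resolves, transparently, the label-convention ambiguity in
clinical reports that quote NMIBC sensitivity while modelling MIBC as
positive. AUC is the rank-based Mann–Whitney estimator with tie correction;
the test suite checks it against explicit trapezoidal integration of the
enumerated ROC curve (to `1e-10`) and against pROC. Confidence intervals are
stratified percentile bootstrap (`B = 2000` by default; class-stratified so
every resample contains both classes). Correlated ROC curves are compared
with the DeLong test (implemented from the structural-component covariance
form) with Bonferroni correction capped at 1; tests validate it against
pROC's DeLong implementation, against a paired permutation oracle, and
against its nominal type-I error on null simulations. Cohort splits are
seeded, stratified, and accept either a 6:1:3 ratio or explicit counts
(115/20/49). Percentages in cohort summaries round half-up to one decimal to
match the conventional formatting.

# Saliency maps

`grad_cam()` backpropagates the class score to the layer-1 ReLU activations
of a chosen branch — the deepest point at which the feature map retains the
full 5-phase temporal extent, which is what makes *per-phase* maps possible;
deeper layer-2 targets have already collapsed the phase axis through
pooling. Channel weights are spatially averaged gradients per phase; the
weighted activation map is ReLU-rectified and min–max normalized per phase
(a global-normalization option exists), with a constant map defined as all
zeros rather than NaN. The mid-scale (k = 3) branch is the default target.
Overlays blend a deterministic heat colormap onto the grayscale phase image
and write byte-reproducible PNGs.

# Numerical choices and degenerate inputs

* Normalization epsilon `1e-5`; probability clamp `1e-7`; layer-norm and
  instance-norm backward passes derived analytically and covered by
  finite-difference tests at `1e-4`.
* Max pooling uses floor mode; the phase axis (5 voxels deep) pools to 2 and
  the stride-2 depthwise layer reduces it to 1.
* Softmax subtracts row maxima before exponentiation; attention inputs are
  checked finite.
* Empty tumor masks, single-class cohorts, zero pooled variance, non-integral
  window counts, out-of-bounds ROIs and non-finite losses all raise explicit
  errors with the failing quantity named.
* Ties: key-slice selection takes the lowest index; max pooling the earliest
  position; both documented and tested.

# Desk-scale configurations and what the tests show

CPU-scale experiments (the test suite and the worked examples) use
`desk_model_config()`: the identical architecture at 112 x 112 input
(feature dimension 196), token allocation (16, 32, 64) over 9 windows of
`W = 16, S = 12, L = 4`, one transformer block, unit feed-forward expansion,
context-token feed-forward. Phantom experiments use 200 patients split
6:1:3, batch 8, AdamW at `1e-3`, with the default augmentation policy and
checkpoint selection on validation AUC. These sizes are the package's
standard demonstration scale; the budget-sized default configuration is used
for the architecture-contract checks (token shape, parameter count).
Passing tests on phantom data demonstrate that the implementation can learn
the phantom's spatiotemporal class structure end-to-end and that the full
model outperforms its single-module ablations there; they say nothing about
clinical performance on real cohorts.

# Known limitations

* N4 bias-field correction is a documented external preprocessing hook, not
  reimplemented here.
* Automatic bladder segmentation is out of scope; ROIs are inputs.
* The conditional-GAN minority synthesis described alongside the original
  cohort is replaced by oversampling plus classical augmentation.
* Baseline networks (VGG/ResNet/DenseNet/ViT) are not trained here; the
  comparison tooling accepts externally produced score files
  (`compare_models()`).
* The phantom is a single-slice, circle-geometry idealization; see above.
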