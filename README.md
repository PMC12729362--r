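# windmri

Classification of bladder-tumor muscle invasion from multiphase dynamic
contrast-enhanced MRI (DCE-MRI), for imaging researchers who want a fully
inspectable, CPU-runnable implementation of a transformer-fused multiscale
3D convolutional classifier — together with the cohort statistics (rank
AUC, stratified bootstrap CIs, DeLong tests) and Grad-CAM saliency tooling
such a study needs, and a synthetic contrast-enhancement phantom so every
stage runs without clinical data.

## The model

One patient contributes a key-slice stack `X ∈ R^{224×224×5}`: per
acquisition phase (0/30/60/90/300 s post-contrast), the slice with the
largest tumor burden, Z-score normalized with training-cohort tumor
statistics, cropped to the bladder ROI and resized.

1. **Multiscale token extraction.** Three parallel dual-layer 3D
   convolution branches (kernels 1³, 3³, 5³; standard conv → norm → ReLU →
   pool, then depthwise + pointwise conv → norm → ReLU → pool) reduce the
   spatial side by 8 and collapse the phase axis, emitting
   `X'' ∈ R^{448×784}` — 448 tokens of 784 features.
2. **Fused window attention.** The token sequence is split into
   `F = (T−W)/S + 1` overlapping windows (default `W=64, S=48, L=8`, so
   `F=9`); each window carries fringe tokens in its keys/values and a
   learnable context/auxiliary token. Per window, multi-head scaled
   dot-product attention `softmax(QKᵀ/√d)V` with `Q = W_q{c,x}` and
   `K = V = W_k{c,a,x,b}`; the window context outputs are fused by their
   arithmetic mean `F_o = (1/F)Σc_i` plus layer normalization.
3. **Head.** `y_p = sigmoid(w·F_o + b)`, trained with mean binary
   cross-entropy; the non-invasive class is negative.

The default configuration totals 27.74 M trainable parameters. All network
layers (3D convolutions, pooling, normalizations, windowed attention,
backpropagation, AdamW) are implemented in the package (R + Rcpp), making
every gradient testable against finite differences.

## Worked example

A phantom cohort, an end-to-end desk-scale run, and the printed numbers:

```r
library(windmri)

co <- simulate_cohort(phantom_config(n_patients = 60, seed = 7))
co
#> phantom_cohort: 60 patients (16 invasive), 256x256 px, seed 7

cohort_summary(ifelse(co$manifest$label == 1, "invasive", "noninvasive"))
#> # A tibble: 2 × 3
#>   group       count percent
#>   <chr>       <int>   <dbl>
#> 1 invasive       16    26.7
#> 2 noninvasive    44    73.3

res <- run_pipeline(pipeline_config(
  phantom = phantom_config(n_patients = 60, seed = 7),
  train = list(epochs = 4, batch_size = 8, lr = 1e-3, patience = 4),
  seed = 7))
res$report
#> # A tibble: 4 × 4
#>   metric      estimate ci_low ci_high
#>   <chr>          <dbl>  <dbl>   <dbl>
#> 1 sensitivity    0.2    0       0.6
#> 2 specificity    0.846  0.692   1
#> 3 accuracy       0.667  0.5     0.833
#> 4 auc            0.585  0.253   0.893
```

The report rows are sensitivity/specificity/accuracy at the 0.5 threshold
and the rank-based AUC on the 18 held-out patients, each with a stratified
bootstrap 95% interval — at this deliberately short demonstration schedule
(60 patients, 4 epochs, no augmentation) the classifier is barely better
than chance, and the wide intervals say so. The 200-patient schedule used by
the test suite — 15 epochs with augmentation and checkpoint selection on
validation AUC — reaches held-out AUC above 0.9 on the phantom task, with
both single-module ablations clearly below the full model; see
`tests/testthat/test-acceptance.R`.

Interpretability on the trained fit (`run_pipeline()` already exports one
panel; `grad_cam()` works on any preprocessed stack):

```r
sal <- res$saliency[[1]]   # grad_cam(res$fit, stack): one heatmap per phase
autoplot(sal)              # facetted per-phase attention panels
# overlay(sal$maps[[p]], image) + write_overlay_png() render Figure-style PNGs
```

Model comparison from score files (CSV: patient_id, score, label,
model_name):

```r
compare_models(scores, bonferroni_m = 4)   # pairwise DeLong tests
```

A thin CLI wraps the same functions
(`inst/cli/windmri simulate --n 200 --seed 7 --out dir/`; subcommands
`simulate`, `preprocess`, `train`, `evaluate`, `compare`, `explain`,
`ablate`, `pipeline`).

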