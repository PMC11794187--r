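---
title: "Model, design choices and numerical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, design choices and numerical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The detector in one page

`longandet` assembles a single-stage, anchor-free detector for clustered
fruit. The baseline skeleton is the familiar s-scale design: a backbone of
strided conv units and C2f cross-stage blocks ending in fast spatial
pyramid pooling (SPPF), a PAN-FPN neck that fuses three scales top-down and
bottom-up, and a decoupled head that predicts, per grid cell at strides
8/16/32, a class logit and four edge distances as 16-bin discrete
distributions (distribution-focal regression). Four modifications define
the package's subject:

1. the first conv + C2f pair becomes a densely connected **DenseAMA** stage;
2. the last three backbone C2f blocks become **C2f-Faster-AMA** blocks built
   on partial convolutions;
3. every neck fusion block becomes a **VOVGSCSPC** block built on GSConv;
4. the box-overlap term of the training loss becomes **Inner-SIoU**.

All primitives run on a small reverse-mode autodiff tape over base-R arrays
(layout `H × W × N × C`), with convolutions evaluated as per-offset BLAS
matrix products. This keeps the package dependency-free and CPU-only; it is
not a speed claim.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `ama_config()` `a, b, g` | 2, 1, 4 | coefficients of the adaptive 1-D kernel map `K = round_odd((a·C^0.35 + b)/g)`; defaults give K = 3 at 64 channels, K = 5 at 512 |
| `dense_config()` `growth_rate, num_layers, bottleneck_factor` | 16, 3, 3 | sizing of the dense stage; see the calibration note below |
| `pconv_spec()` `partial_ratio` | 1/4 | fraction of channels the partial conv touches (the published FasterNet default; the source design states none) |
| `gs_spec()` `dw_k` | 5 | depthwise kernel of GSConv (slim-neck convention) |
| `siou_params()` `ratio` | 1.0 | inner-box scale; 1.0 reduces Inner-SIoU to plain SIoU. The admissible range is [0.5, 1.5]; the experimental value is not published, so the neutral element is the default |
| `siou_params()` `theta` | 4 | shape-cost exponent (the published SIoU genetic-search optimum) |
| `train_detector()` `lr0, lrf` | 0.01, 0.01 | initial learning rate and final fraction (terminal rate 1e-4), linearly annealed — the published schedule |
| `forward_predict()` `conf_thresh, nms_iou` | 0.25, 0.45 | common detector post-processing defaults; the source is silent |

# Calibration of the dense stage

The dense stage's sizing is the one deliberately calibrated quantity. The
design leaves `growth_rate`, `num_layers` and the bottleneck width open
while fixing two budgets for the assembled single-class model: about 8.8 M
parameters and about 28.2 GFLOPs at 640×640. Everything outside the dense
stage is pinned by the architecture (the baseline assembles to 11,135,971
parameters; the partial-conv swap alone gives 9.70 M and the neck swap
alone 10.39 M, matching their printed budgets with no free knobs). A grid
search over (layers, growth, bottleneck factor) then minimizes the joint
relative deviation from the two budgets; (3, 16, 3) is the optimum and is
frozen in `dense_config()`. Because the dense layers run at stride 2
(320×320 cells at the reporting resolution), they are compute-heavy per
parameter, which is exactly what lets the full model keep its FLOPs while
shedding a fifth of its parameters. The attainable floor is ~8.92 M even
with an empty dense stage, so the assembled total (8.95 M) sits ~1.7% above
the printed 8.8 M; the FLOP count (27.89 G) sits ~1.1% below 28.2 G.

# Design choices where the source was open

- **Hard-sigmoid cases.** The printed piecewise definition is typographically
  corrupted; the implementation is the standard `clamp((x+3)/6, 0, 1)`, the
  only reading consistent with `x·ReLU6(x+3)/6`.
- **AMA fusion.** The block describes two pooled weight vectors but not
  their combination. The two 1-D-convolution responses are summed before a
  single sigmoid (CBAM-style), and the 1-D kernel is shared between the
  average and max branches, which keeps the parameter count at K per block.
  Kernel rounding is to the nearest odd integer, ties toward the larger.
- **Dense transition compression.** The transition is described as
  BN → H-swish → AMA → average pool; a 1×1 compression conv is added before
  the pool because without it the stage cannot match the downstream
  backbone width (and the named DenseNet121 basis compresses in its
  transitions).
- **PConv channel choice.** "First or last consecutive channels" — fixed to
  *first* for determinism. The AMA gate in the Faster block sits on the
  branch output, before the residual add. The inner activation is ReLU
  (FasterNet convention), config-exposed.
- **VOVGSCSPC width.** Read literally, the block equations tie the hidden
  width to the *input* channel count; at the neck fusion points (input 384
  or 768 channels, output 128–512) that would *increase* parameters, while
  the swap's stated effect is a reduction. The implementation follows the
  published slim-neck convention — hidden width = half the *output* width —
  which coincides with the equations in the equal-width case they assume
  and reproduces the printed budget. The GSBottleneck's two GSConvs use
  dense kernels 1 and 3.
- **Inner-box corner equations.** Two of the four printed anchor-corner
  equations contain copy typos (a ground-truth center in an anchor edge;
  one edge printed twice); the implementation is the symmetric form.
- **Head and assigner.** The head keeps the baseline decoupled anchor-free
  form with distribution-focal regression — the design changes only the
  box-overlap loss term. Training uses a center-inside assigner (a cell is
  positive for the nearest ground-truth box containing its center, provided
  the required edge distances are representable within the 16-bin range)
  rather than a dynamic task-aligned assigner; at the package's problem
  sizes the simpler rule is sufficient and fully deterministic.

# Numerical choices

- **Angle cost.** `Λ = 1 − 2 sin²(asin(x) − π/4)` with `x = c_h/σ` clamped
  to [0, 1]; coincident centers (σ below `eps = 1e-9`) return Λ = 0. In the
  analytic gradient the argument is capped at `1 − 1e-7` to avoid the
  square-root singularity; min/max/abs kinks carry one-sided subgradients.
- **Degenerate boxes.** Zero union returns IoU 0; a zero enclosing extent
  or a dimension degenerate in both boxes contributes 0 to the distance and
  shape costs. All components are finite for all finite boxes.
- **Intersection clamp.** The printed inner-box intersection can go
  negative for disjoint boxes; it is clamped at 0.
- **Initialization.** Conv weights are He-normal; the classification bias
  starts at `log(0.01/0.99)` so an untrained model predicts detections
  rarely; box-bin biases start at 1. One integer seed fixes initialization
  and every stochastic part of data generation and training.
- **Batch normalization.** Training mode uses batch statistics with the
  full backward pass; evaluation uses running statistics (momentum 0.1).
- **FLOP convention.** 2 × multiply-accumulates over convolutions and
  linear maps only, the convention under which detector compute budgets are
  printed; pooling, normalization and activations count zero.
- **AP integration.** All-point precision-envelope integration, matching
  the baseline detector family's evaluator; matching is greedy in score
  order, one-to-one per image and class, ties broken deterministically.

# The synthetic data, and what passing tests do not show

`synth_orchard()` emulates the imaging conditions the detector is meant
for: textured green canopy backgrounds, 1–6 clusters per image, each a
clump of 5–20 shaded warm-colored circles, optional elongated occluder
strokes crossing a cluster, and per-image gamma lighting spanning the
augmentation table's highlight-to-deep-shadow range. Ground truth is the
bounding box of each cluster's rendered pixels, so labels are correct by
construction, and byte-identical regeneration from the seed is tested.

It does **not** emulate real orchard difficulty: no perspective or depth
of field, no cluster-on-cluster overlap statistics of real trees, no leaf
textures or specular highlights, no label noise. Passing the seeded smoke
training (the width-/8 model overfitting four 160×160 images to training
mAP@0.5 ≥ 0.95 in 200 full-batch steps) demonstrates that the assembled
network, loss, gradients, assigner and decoder are mutually consistent —
it says nothing about detection accuracy on real longan imagery, which
would require the original UAV dataset and GPU-scale training and is out
of scope here.

# Problem sizes used by the test suite

Module tests run on feature maps of a few thousand elements. The
accounting checks build the four full-size model variants and run one
640×640 forward pass each for the FLOP meter. The loss oracle compares
1,000 grid-aligned random box pairs against exact pixel counting; the
metric oracle compares 200 random tiny scenes against a re-matching AP
enumerator. The smoke training uses 4 images at 160×160 for 200 steps
(about 4 minutes on one CPU). These sizes were chosen as the smallest that
exercise every code path meaningfully.

# Known limitations

- Pure-R execution is orders of magnitude slower than a tensor framework;
  full-resolution training is out of reach (and out of scope).
- The training loop is full-batch with Adam or plain SGD; no mosaic or
  flip augmentation inside the loop, no EMA of weights.
- `vovgscspc` implements the single-bottleneck form used at the neck
  fusion points; chained bottleneck counts are not supported.
- Weight serialization is R-native (`saveRDS`); there is no interchange
  with other frameworks.
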