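---
title: "Methods: a two-channel shifted-window transformer for leaf disease classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-channel shifted-window transformer for leaf disease classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`swinleaf` classifies RGB leaf images into 22 disease/health categories
with two independent hierarchical transformer channels fused by
concatenation. The design rests on two observations about leaf-disease
imagery: lesions are dispersed over the whole blade (so the classifier
must relate distant image regions, which windowed self-attention does at
linear cost in the token count), and lesion *boundaries* are the most
class-discriminative structure (so a second channel consumes an explicit
edge map rather than the raw image).

The upper channel receives the raw image; the lower channel receives
`make_edge_input()`: BT.601 grayscale, cross-correlation with the Sobel
pair `G_x`, `G_y = t(G_x)`, per-pixel magnitude `sqrt(gx^2 + gy^2)`,
per-image max rescaling to `[0, 1]`, replicated to three channels. The
kernels are model parameters: every step of that map is differentiable,
so training refines them ("learnable Sobel"). No parameter is shared
between the channels. Pooled per-channel features (length `8C` each) are
concatenated upper-first and mapped by one fully-connected layer to class
logits; training minimizes cross-entropy against hard labels or the soft
labels produced by Mixup/CutMix.

Each channel follows the standard shifted-window recurrence: layer norm,
W-MSA or SW-MSA, residual add, layer norm, two-layer GELU MLP, residual
add. Stages of depths 2/2/6/2 alternate standard and shifted blocks
(starting standard; even depths keep the pairing aligned), and patch
merging between stages concatenates 2×2 token neighborhoods,
layer-normalizes and reduces them linearly from `4C` to `2C`.

## Design choices where the design was open

* **Edge-channel assembly.** How the edge information is combined into a
  channel input admits several readings (overlaying edges on the image,
  per-color edges, magnitude only). We use the magnitude map alone,
  replicated into 3 channels, so both channels share one patch-embedding
  geometry; the choice is isolated behind `make_edge_input()` and can be
  swapped without touching anything else.
* **Channel widths.** Writing the stage outputs as H/4×W/4×C … H/32×W/32×C
  only makes sense hierarchically if the width grows at each merge; we
  double it (96/192/384/768), the convention of the Swin-T backbone this
  architecture instantiates. A literal constant-C reading would make the
  4C→2C merge reduction dimensionally inconsistent.
* **Head order.** "Softmax classifier, average pooling, fully-connected
  layer" is implemented as pool → concatenate → fully-connected → softmax;
  pooling must precede the head for the dimensions to work, and fusion
  happens after the stages, so per-channel pooling comes first.
* **Final pooling.** Global average pooling is taken over the spatial
  token grid, yielding one channel-width vector per channel (a pooled
  "first C components" reading over an N-sized spatial vector is
  dimensionally inconsistent and was rejected).
* **Shifted-window masking.** The cyclic shift rolls the grid by
  `floor(M/2)`; the regular tiling is then reused. Pairs of tokens that
  are adjacent *only because of the wrap-around* (they come from opposite
  image edges, i.e. from disjoint pre-shift windows) are blocked with
  `-Inf` logits, which makes their post-softmax mass exactly zero, not
  merely small. Tokens from different pre-shift windows that are truly
  adjacent in the image *are* allowed to attend — that cross-window flow
  is the purpose of shifting; masking exists only to stop the artificial
  wrap-around adjacency.
* **Attention details.** Learned relative position bias per head (table of
  size `(2M-1)^2 × heads`, toggleable), heads 3/6/12/24, MLP ratio 4,
  GELU (`x · pnorm(x)`). These are the Swin-T defaults, adopted because
  the backbone is named, not derived.
* **Pretrained import.** `load_pretrained()` accepts a flat archive keyed
  by the public Swin checkpoint names (`swin_name_map()` documents the
  correspondence and the layout conversions) and can fill the upper
  channel, the lower, or both — whether the edge channel should also start
  from natural-image weights is genuinely open, so the loader supports
  both. The classification head and the Sobel kernels are never imported.
* **Metric averaging.** Headline precision/recall/F1 are macro averages
  (uniform over classes), the convention for imbalanced benchmarks; micro
  averages are also reported. For single-label classification the micro
  precision, recall and F1 all collapse to trace/total, which equals the
  overall accuracy — the suite asserts this identity on random confusion
  matrices. (The pooled one-vs-rest accuracy of Eq.-style counts does
  *not* equal trace/total for more than two classes; we report the
  trace/total quantity.)
* **Augmentation schedule.** Flip probability 0.5 (horizontal only),
  jitter half-widths 0.4/0.4/0.4 and hue 0.1, Mixup `Beta(0.8, 0.8)`,
  CutMix `Beta(1, 1)`; each batch applies at most one of Mixup/CutMix,
  chosen with equal probability. Augmentation acts on the raw image
  *before* the edge channel is derived, so both channels always see the
  same geometry. CutMix mixes labels with the exact visible-area fraction
  after border clipping, not the drawn lambda.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `image_size` | 224 px | input side length (square) |
| `patch_size` | 4 px | token granularity; token dim = `3·patch²` = 48 |
| `embed_dim` C | 96 | stage-1 width; doubles at each merge |
| `window_size` M | 7 tokens | attention locality; clamped to the stage grid |
| `depths` | 2/2/6/2 | blocks per stage (12 total) |
| `heads` | 3/6/12/24 | attention heads per stage |
| `mlp_ratio` | 4 | MLP hidden-width multiplier |
| `drop_path_rate` | 0 | stochastic depth (0 keeps runs deterministic) |
| `batch_size` | 8 | training mini-batch |
| `learning_rate` | 1e-4 | Adam step size |
| `epochs` | 100 | training passes |
| `folds` | 10 | cross-validation folds |
| `clip_norm` | 5 | global gradient-norm ceiling |

The training defaults are the study recipe (batch 8, Adam at 1e-4, 100
epochs, 10-fold stratified cross-validation); Adam moments are the
standard 0.9/0.999.

## Numerical choices

* **Zero-initialized residual branches.** The attention and MLP *output*
  projections start at zero, so every block is initially the identity and
  the fused features reduce to pooled patch embeddings. This removes the
  long uniform-logit plateau that random residual branches produce at
  small scale; the projections receive nonzero gradients from the first
  step, after which the blocks differentiate. Everything else is
  truncated-normal (sd 0.02, clipped at 2 sd), biases zero, layer-norm
  gains one.
* **Gradient clipping.** Global-norm clipping (default 5, the standard
  stabilizer for this backbone family) guards against the rare late-run
  loss spikes of very-small-batch Adam.
* **Edge-map degeneracies.** On a constant image the convolution responses
  are accumulated floating-point residue (~1e-16), and rescaling by such a
  maximum would blow noise up to 1; magnitudes with maximum ≤ 1e-9 are
  therefore treated as exactly zero. The per-image max is differentiated
  through its argmax pixel (the subgradient of the running maximum), and
  pixels of zero magnitude get zero gradient (the norm is not
  differentiable there).
* **Masking.** Blocked attention logits are `-Inf`, giving exactly zero
  probability after the softmax (a diagonal entry is always admissible,
  so no row is entirely blocked). Layer norm uses eps 1e-5.
* **Ties and degenerate geometry.** Argmax prediction breaks ties toward
  the lowest class index. When a stage grid is no larger than the window
  (e.g. the 7×7 final stage), shifting is a no-op and is skipped.
  Stratified folds deal classes round-robin with a rotating starting
  fold, so per-class counts across folds differ by at most one; classes
  smaller than `k` warn and stratify best-effort.

## The synthetic-data generator

`generate_dataset()` renders the 22-class manifest (1,185 … 40 training
images per class; totals 11,603 train / 1,668 test) at any `scale`, with
`ceiling(scale · count)` images per class, deterministic per-image seeds,
and stable lexicographic file naming (test files continue the per-class
numbering so the two trees never share a file name). Each image is a
textured background, a rotated elliptical blade whose hue encodes the
plant (with a small per-class offset), and — for diseased classes —
lesions placed by a seeded point process *uniformly across the whole
blade*, with severity encoded as lesion density (healthy 0, general 10,
serious 28 expected lesions). Each image carries its lesion mask as an
attribute so tests can audit lesion area and dispersion directly.

The generator emulates the *structure* of the benchmark — class
imbalance, severity pairs, blade-wide lesion dispersion, class-specific
color statistics — and deliberately not its photographic content: no
venation, specularity, occlusion, scale variation or background clutter.
Passing tests therefore demonstrate that the pipeline is mechanically and
statistically sound (shapes, gradients, masking, determinism, and enough
signal to overfit), not that the model reaches any particular accuracy on
real leaf photographs; the benchmark's headline accuracies require the
original dataset and GPU-scale training, which are out of scope here.

## Problem sizes used by the tests

The suite exercises full Swin-T geometry (224 px, 12 blocks, 55 M
parameters) forward-only; everything involving training or finite
differences runs on reduced configurations chosen as the smallest
geometries that still contain every mechanism (two stages, a merge, a
shifted block, multi-head attention): 8 px/C=4 for gradient checks,
32 px/C=16 for the overfitting run (2 classes × 8 images, batch 4,
learning rate 1e-3, clip 0.5, 30 epochs — the tighter clip makes
very-small-batch steps behave like normalized gradient descent, which we
found necessary and sufficient for reliable escape from the initial
saddle across seeds). Attention is checked against a dense per-window
oracle at the real stage-3 geometry (14×14 grid, M = 7).

## Known limitations

* Pure-R execution: a full 224 px dual forward takes a few seconds per
  image on one CPU; full-scale 100-epoch training is not practical in R
  and is not attempted — the training loop is exercised at reduced scale.
* The edge channel duplicates information already present in the raw
  channel; the architecture accepts that redundancy by design.
* `drop_path_rate > 0` makes training stochastic per call; the
  reproducibility contract then holds only for a fixed RNG stream.
* Hue jitter converts through HSV per pixel and is the slowest
  augmentation; keep `hue = 0` if throughput matters.
* No learning-rate schedules, mixed precision or multi-device support.
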