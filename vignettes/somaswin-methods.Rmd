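---
title: "Methods: shifted-window transformer segmentation of neuronal somas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shifted-window transformer segmentation of neuronal somas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantifying neuronal soma size in thick (350-450 µm) acute brain slices
imaged by two-photon microscopy is hard for classical segmentation:
GCaMP6s brightness is activity dependent (dim under baseline aCSF,
bright under NMDA perfusion, intermediate during washout), the neuropil
gives a dense low-contrast background, and somas from different depth
planes overlap. `somaswin` implements an automated 2D instance
segmentation pipeline for this setting: synthetic training data built
from sparse annotations, maximum-intensity-projection (MIP)
preprocessing, a hierarchical shifted-window (Swin) transformer feature
extractor, a trainable per-pixel instance head with confidence
thresholding, and a quantitative evaluation protocol.

## Synthetic data generation

Exhaustive manual annotation of every soma in a training set is
impractical, so training images are synthesized by copy-paste-blend:

1. **Background tiles** are rectangular crops of non-somatic regions
   (`extract_tiles()`), or parametrically rendered neuropil textures
   (`render_tile_bank()`: smoothed Gaussian noise around a dim mean,
   default 0.15 with texture SD 0.04).
2. **Synthetic backgrounds** are mosaics of shuffled tiles placed until
   the canvas is covered, blended with normalized feathered weights so
   seams are continuous (`compose_background()`).
3. **Annotated cells** are either user-supplied crops with masks
   (`annotated_cell()`) or parametric somas (`render_cell()`): an
   ellipse with a Gaussian-falloff profile whose mask is the
   half-maximum region, so a circular cell of nominal radius r has mask
   area close to the analytic disc area. The perfusion condition sets
   the peak-intensity regime — baseline [0.3, 0.6], washout
   [0.45, 0.8], NMDA [0.6, 1.0] — encoding the observed ordering
   nmda >= washout >= baseline, all above the neuropil mean.
4. **Pasting** (`paste_cells()`) places each cell at a uniform offset,
   rejecting placements whose instance-mask IoU with an already placed
   instance exceeds `max_pairwise_overlap_iou` (default 0.1, 50
   retries, then the cell is skipped and recorded). Blending uses
   signed-distance feathered alpha: opaque inside the mask eroded by
   `feather_width` (default 3 px), transparent beyond the mask dilated
   by the same amount. With `feather_width = 0` the paste is hard, and
   pixels inside the mask equal the cell crop exactly.
5. Optional **salt-and-pepper corruption** (`add_salt_pepper()`)
   replaces each pixel independently with 0 or 1 (equal odds) with the
   configured density, for robustness experiments.

Blending design: feathered alpha compositing was chosen over gradient-
domain (Poisson) blending because it is deterministic, cheap, and
sufficient to avoid unnatural contrast steps at paste boundaries;
gradient-domain blending would also distort the interior intensities
that carry the condition signal.

Defaults emulate the target imaging setup: 512 x 512 frames, 5-20 somas
per frame (the visual density of the real slices), mean soma radius
6-14 px, axis ratio 0.6-1. The per-image cell count and overlap policy
are not constrained by published values, so they are configuration, not
claims. Reproducibility is strict: a single master seed derives
per-image child seeds (`derive_seed()`), and the same
`generator_config` reproduces byte-identical image and annotation
files.

What the generator does *not* emulate: motion artifacts,
photobleaching, depth-dependent scattering, dendrites/axons attached to
somas, and true neuropil structure. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and
learnable, not that a model trained here reaches any particular
accuracy on real slices.

## Preprocessing

Z-series (512 x 512, 2 µm steps in the reference setup) are reduced to
network inputs in the order: per-slice background subtraction, per-slice
median smoothing, windowed maximum-intensity projection, CLAHE on each
projection (`preprocess_stack()`).

- **Background subtraction** is a rolling-ball analog: grayscale
  morphological opening with a disc structuring element (default radius
  50 px, the common ImageJ default) subtracted and clipped at zero. The
  exact algorithm and radius used originally are not recoverable, so
  both are configurable.
- **Median smoothing** uses a disc neighborhood of radius 2 px with
  reflected borders.
- **MIP** reduces consecutive windows of 10 slices (20 µm at 2 µm
  steps — the depth over which a soma's maximal cross-section appears)
  by the per-pixel maximum. Trailing partial windows are kept and
  flagged rather than silently dropped; `depth_um` always equals the
  window's slice count times the z-step.
- **CLAHE** uses a normalized clip limit of 0.01 on an 8 x 8 tile grid
  (configurable); constant images pass through unchanged.

Per-slice filtering before projection (rather than filtering the
projection) follows the natural reading of the processing order; both
orders are available through the configuration toggles.

## The backbone

The feature extractor is a four-stage hierarchical shifted-window
transformer implemented from scratch in matrix algebra:

- `patch_partition()` cuts the grayscale image into non-overlapping
  4 x 4 patches; each patch is one token of dimension 16 (zero-padding
  to multiples of the patch size; a 512 x 512 frame gives 128 x 128
  tokens).
- `linear_embed()` projects tokens to C channels (C = 96 in the
  reference configuration; C controls model size), followed by layer
  normalization.
- Each **Swin block** computes `x + MSA(LN(x))` then `x + MLP(LN(x))`
  with a two-layer GELU MLP (expansion 4). Self-attention is scaled
  dot-product multihead attention restricted to M x M token windows.
  Blocks alternate between the regular partition (W-MSA) and a
  partition cyclically shifted by floor(M/2) (SW-MSA); the shifted pass
  carries an attention mask that forbids attention between tokens that
  wrapped around from non-adjacent regions, which is what lets windows
  exchange information without quadratic cost. A learned relative
  position bias (a (2M-1)^2 x heads table indexed by token offset) is
  added to the logits by default and can be disabled.
- `patch_merge()` concatenates each 2 x 2 token group (4C channels),
  layer-normalizes, and projects to 2C: resolution halves, the token
  count drops by exactly 4. Odd grid dimensions are zero-padded on the
  right/bottom so no tokens are discarded.

The four stages yield feature maps at H/4, H/8, H/16, H/32 with C, 2C,
4C, 8C channels. Per-stage depths default to 2-2-6-2 and heads to
3-6-12-24 (head dimension 32), with 2-2-2-2 available; the window size
defaults to M = 7. These follow the small ("tiny") configuration of the
published Swin family because the exact depths and window size used in
the source study are not recoverable from its text; all are
configurable and recorded in checkpoints.

Correctness is established structurally: window partition/reverse and
cyclic shift round-trip exactly; with a window covering the whole grid
and no shift, windowed attention equals a brute-force global attention
oracle to within 1e-5; in shifted mode, attention weight between tokens
from non-adjacent pre-shift regions is exactly zero (verified by a
label-propagation probe with identity value projections).

## The detector head

How instances are produced from backbone features is an open design
choice (the source text specifies only that segmentations emerge with
per-instance confidence scores). `somaswin` uses a dense-prediction
head: each pixel's feature vector is its raw intensity, its Gaussian-
smoothed intensity, and the (nearest-neighbor upsampled) backbone
features of the token covering it, from the configured stages (default
1-2). A logistic scoring layer maps features to a foreground
probability; instances are connected components of the thresholded
probability map (components below `min_area`, default 9 px, are
dropped), and each instance's confidence is its mean foreground
probability. A region-proposal/mask-head decoder in the Mask R-CNN
style would need a full convolutional training framework; the dense
head keeps every contract of the module — per-instance masks, scores,
nested confidence thresholding — while remaining trainable with exact
hand-derived gradients.

Training (`train_model()`) minimizes class-weighted binary
cross-entropy between the probability map and the union of ground-truth
instance masks, with Adam (default lr 0.05, cosine decay; foreground
pixels are up-weighted by the background/foreground ratio, capped at
20). The backbone is a frozen feature extractor, so per-image features
are computed once and cached; one optimization step consumes one image
and every step's loss is logged. Training aborts with a diagnostic on a
non-finite loss, and checkpoints restore bit-identical predictions.

The default inference threshold is 0.05, the operating point that
favors recall; raising it trades detections for precision, and
`filter_by_score()` guarantees that the detections at a higher
threshold are a subset of those at a lower one.

## Evaluation protocol

- **Dice** `2|X∩Y|/(|X|+|Y|)` and **IoU** `|X∩Y|/|X∪Y|` are exact pixel
  ratios, related by `dice = 2*iou/(1+iou)`; the overlap of two empty
  masks is an error, never a silent zero.
- **Matching** (`match_instances()`): each ground truth is paired with
  the unassigned prediction of highest Dice; a pairing is a true
  positive when IoU exceeds 0.5. Ground truths are processed in
  descending best-Dice order with ties to the lowest index, and
  assignment is strictly one-to-one — the deterministic completion of a
  per-ground-truth best-overlap rule that does not itself specify
  contention resolution. Unmatched predictions are false positives,
  sub-typed doublet (covering >= 2 ground truths with IoU > 0.2 each),
  wrong boundary (best IoU in (0, 0.5]), or background. Doublet is
  tested before wrong boundary because a doublet's per-soma IoUs
  typically fall in the wrong-boundary interval; the numeric sub-typing
  rules are package choices (the categories are described only verbally
  in the source) and are configurable.
- **Precision** TP/(TP+FP), **recall** TP/(TP+FN) and **yield rate**
  (correct detections over ground-truth somas) are exact ratios with
  explicit errors on empty denominators.
- **Area agreement** (`area_agreement()`) reports the mean and SD of
  predicted-minus-manual somatic areas, the OLS slope/intercept of
  predicted on manual, and the squared Pearson correlation (flagged
  undefined for constant manual areas). Areas require a user-supplied
  lateral pixel size, which the reference imaging setup does not pin
  down.
- **Threshold sweeps** (`threshold_sweep()`) tabulate, per confidence
  cutoff, the total detections and the percentages of correct /
  wrong-boundary / background-plus-doublet verdicts; totals are
  non-increasing in the cutoff by construction.

## Numerical choices and degenerate inputs

Softmax logits are max-shifted before exponentiation; masked pairs get
-Inf logits (a token always attends at least to itself, so no row is
empty). Layer normalization uses a 1e-5 variance floor. Weight
initialization is truncated normal (sd 0.02, clipped at 2 sd) with zero
biases, deterministic given the seed. All RNG flows through a single
master seed via `derive_seed()`, which keeps every derived seed a valid
31-bit integer. Images are `[0, 1]` doubles everywhere; files are 8-bit
PNG or 16-bit uncompressed TIFF, and masks serialize as uncompressed
column-major RLE for bit-exact round trips.

## Problem sizes used in tests

The test and acceptance suites run the study at reduced scale, chosen
so the full pipeline exercises every code path in seconds: 64 x 64
frames with 2-4 disjoint bright somas, a tiny backbone (C = 32, depths
1-1-1-1, window 4, heads 2-4-8-16), 16 training images and 6 epochs.
Under these conditions the trained detector reaches recall above 0.95
at IoU > 0.5 with mean Dice near 0.9 on held-out synthetic frames —
figures the acceptance script recomputes from scratch on every run.
The published headline accuracies of the original trained model are not
reproducible here (the underlying slice data and weights are not
released), which is why the acceptance suite substitutes property-based
checks: oracle-verified metrics, attention equivalence, round-trip
identities, monotone thresholding, byte-reproducible generation, and
scaled-down learnability.

## Known limitations

- 2D only; somas are measured on projections, not volumes.
- The parametric cell bank renders smooth ellipses; real somas have
  irregular boundaries and attached processes. Import real crops via
  `annotated_cell()` for realistic banks.
- The dense head cannot separate touching somas whose probability
  regions merge (they surface as doublet false positives, which the
  evaluation protocol counts explicitly).
- Training optimizes the head only; the backbone is a fixed random
  hierarchical projection. This is sufficient for the high-contrast
  synthetic regime and keeps desk-scale training exact, but real-data
  performance would benefit from end-to-end optimization.
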