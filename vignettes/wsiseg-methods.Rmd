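---
title: "Methods: cascaded patch classification and U-Net refinement for whole-slide tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded patch classification and U-Net refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Whole-slide images (WSIs) of hematoxylin–eosin stained tissue are far too
large to segment directly at full resolution, while aggressive down-sampling
destroys the cellular detail that distinguishes tumor from reactive or
inflamed tissue. `wsiseg` implements the common compromise as a two-stage
cascade:

1. **Patch-wise classification (PWC).** The slide is divided into
   non-overlapping 224×224 tiles. Tiles that are mostly background glass are
   discarded by a tissue detector (a threshold on smoothed colour-gradient
   magnitude: glass is flat, tissue is textured). Each kept tile receives a
   tumor probability from a convolutional classifier built by *fusing two
   truncated backbones*: both branches read the identical patch, each ends in
   global average pooling, the pooled features are concatenated, and a single
   2-unit softmax dense layer decides. The per-tile probabilities form a
   coarse heatmap.
2. **Refinement.** The heatmap is resized (bilinear) to a fixed frame,
   concatenated with a down-sampled RGB view of the slide into a 4-channel
   image, and refined by a lightweight U-Net that outputs per-pixel 2-class
   softmax probabilities. Thresholding the tumor channel at 0.5 (equivalent
   to arg-max with two classes) gives the segmentation, which is then
   post-processed (fragment removal, morphological opening, median blur).

The cascade assumes (a) the tumor-vs-non-tumor decision is largely local at
patch scale, and (b) global shape coherence can be recovered at low
resolution from the heatmap plus colour context. Both assumptions are what
the synthetic fixtures (below) are designed to satisfy, and what real tissue
sometimes violates — peripherally inflamed or fibrotic regions are exactly
where this family of models is known to err.

## Multi-lens distortion augmentation

The package's augmentation of note places `N` random "lenses" on an image.
For a lens centred at `(cx, cy)` with radius `R` and strength `S`, every
pixel at distance `r < R` is filled from the source position

    (cx + dx·scale, cy + dy·scale),   scale = 1 − S·(1 − r/R),

with the source coordinate clamped to the image and gathered by nearest
neighbour. The sign of `S` selects locally magnifying or shrinking
(pincushion/barrel-like) behaviour. Three semantics are fixed deliberately
and verified bit-exactly against a literal per-pixel reference loop in the
test suite:

* **Reads come from the original image**, never the running output, so where
  disks overlap the later lens overwrites the earlier one.
* **Clamp, then truncate toward zero** when converting the real-valued
  source coordinate to a pixel index. Truncation is the conventional
  integer-cast reading of such pseudocode; fixing it makes the fast path and
  the reference loop agree to the bit.
* **No interpolation**: every output value is an input value (copy
  semantics), so the augmentation can never hallucinate colours.

Draws per lens occur in the fixed order (cx, cy, R, S) from a single RNG
stream, so one seed pins the complete augmentation. Defaults are `N = 3`,
radii 40–110 px on 224-px patches, strengths in [−0.4, 0.4]; the strength
band is the regime in which the augmentation is reported to help, while the
lens count and radii were never published and are therefore exposed as
ordinary configuration. The rest of the stack (flips, right-angle rotations,
mid-grey-pivot multiplicative contrast, HSV hue shift, additive brightness)
consists of exact pixel permutations and clipped colour maps.

## Tiling and labelling rules

Tiles are laid on a non-overlapping grid (stride = tile size, 0-based,
half-open bounds; ragged margins dropped). The labelling rules are read
literally and kept configurable:

* kept only if tissue fraction is **strictly greater than 0.25**;
* labelled tumor if tumor fraction **≥ 0.05**;
* labelled non-tumor only if tumor fraction is **exactly zero**;
* otherwise (an ambiguous sliver of tumor) excluded from training.

The label function is total, deterministic, and monotone in the tumor
fraction; raising the tissue threshold can only shrink the kept set. Both
properties are asserted in the test suite.

## Networks

Two representations share one container class. *Symbolic* networks enumerate
an architecture layer by layer — exact output shapes, exact parameter counts
(every weight, including non-trainable batch-normalization statistics, the
convention of framework model summaries), FLOPs as 2 × multiply–accumulates
for one 224×224×3 pass. The six standard backbones (VGG19, ResNet101V2,
MobileNetV2, EfficientNetV2-B0, InceptionV3, DenseNet201) are enumerated
this way and the acceptance suite pins their classifier-head parameter
counts to the published table to two decimals (in millions). Head
conventions: global average pooling plus a 2-unit softmax dense layer for
all backbones except VGG19, which keeps its two 4096-unit fully connected
layers with the final layer replaced by 2 units.

The fused classifier's truncation points were chosen in the original study
by an unpublished empirical search, so its exact 13.18 M-parameter figure is
not reproducible; the package's defaults (dense backbone through its third
dense block, 1792 channels; residual backbone through its second stage, 512
channels) keep the fused extractor near 11 M parameters and both cut points
are configurable by layer name. FLOPs are reported but deliberately not
conformance-gated: profiler conventions differ across frameworks, so the
counting convention is stated in the report instead.

*Trainable* networks are desk-scale counterparts authored on a small
matrix-based layer library (im2col convolutions, max pooling, per-channel
normalization, nearest-neighbour upsampling, dense layers; Adam and Adamax;
categorical crossentropy and soft Dice losses). Backward passes are
hand-derived and checked against numerical gradients to ~1e-7 relative
error. Two numerical choices deserve note:

* **Normalization.** The conv blocks normalize per channel over the spatial
  plane of each sample, with learned scale/shift, at both training and
  inference time. At the batch sizes used here (2 for the U-Net) this fills
  the batch-norm slot of the block design without a train/test statistics
  mismatch and keeps inference deterministic.
* **Pooling tie-break.** 2×2 max pooling routes gradients to the first
  maximal element in a fixed scan order.

The tiny U-Net defaults to a 140-px frame, two resolution levels, filters
(8, 16), spatial dropout 0.1, and — like the full-scale design — **no
top-level skip connection** (the ablation that reduced perimeter fragments;
re-enabled with a flag). The symbolic 1120-px U-Net (depth 5, filters
8–128) stays under 2 M parameters, honouring the "lightweight" contract.

## Training procedure

The classifier recipe follows the published one: Adamax, categorical
crossentropy, F1 monitored on the tumor class at threshold 0.5, early
stopping on validation loss with best-weights restoration, and *one random
crop per region per epoch* with the full augmentation stack. The refinement
recipe: Adam, Dice loss (smoothing ε = 1), batch size 2, thresholded-Dice
monitoring, early stopping. Published learning rates (1e-4) and epoch caps
(200/300) are the constructor defaults; patience values were never stated
and default to 20/30. The desk-scale experiment raises the learning rates
(1e-2 / 3e-3) and shrinks the epoch caps (12/30) because its networks are
three orders of magnitude smaller than the originals — at 1e-4 the tiny
networks are still far from convergence within any reasonable desk-scale
budget. A deliberate 40:50 tumor:non-tumor class imbalance is supported as a
sampling ratio and is the experiment's default, mirroring the study's
finding that induced imbalance beat re-weighting schemes.

## Synthetic fixtures: what they emulate, and what they do not

No cohort data are distributable, so every stage is exercised on generated
fixtures: near-white glass; tissue as thresholded low-pass Gaussian noise
(threshold at the quantile matching the requested coverage, so measured
coverage tracks the request); tumor as smooth blobs (radial profile plus
low-pass noise, thresholded) constrained inside tissue; eosin-pink vs
hematoxylin-purple palette with correlated texture. A `separability`
parameter interpolates the tumor colour toward the tissue colour, making
class difficulty controllable and monotone — a property the test suite
checks with a fixed tiny feature classifier. PSA-style annotation is
emulated by rectangular regions found with a summed-area search: tumor
regions must overlap the tumor mask by ≥ 95 %, non-tumor regions contain no
tumor at all. Regions export to QuPath-dialect GeoJSON and round-trip.

What the fixtures do **not** model: nuclei and cellular texture, staining
physics and batch variation, scanner artefacts, tissue folds, necrosis,
infiltrative margins, or multi-resolution pyramids (a single resolution with
a down-sample factor stands in for magnification levels, which the source
recipe never pinned down). Passing the desk-scale experiment therefore shows
that the *pipeline machinery* — tiling, labelling, training loops, stitching,
refinement, metrics — is correct and that refinement genuinely improves a
patch-probability map under clean conditions; it says nothing about
performance on clinical material.

## Desk-scale problem sizes

Fixtures are 1120×1120 (a 5×5 tile grid; the formal default of 4480
down-samples to 1120 by an integer factor 4). The classifier trains on 40
tumor + 50 non-tumor regions of 232 px (one 224-px crop each per epoch); the
U-Net trains on 8 fixtures and is tested on 3 held-out fixtures at a 140-px
refinement frame. These sizes let the whole cascade train from scratch in
roughly three minutes on one CPU while leaving every stage non-trivial: the
stitched 5×5 heatmap alone reaches a Dice of only ~0.75 against ground
truth, and the U-Net must recover the boundary detail from the RGB channels
to pass the ≥ 0.8 acceptance bar (it reaches ~0.95).

## Other conventions and degenerate inputs

* Dice and IoU between two empty masks are defined as 1 (perfect
  agreement); empty vs non-empty is 0. The Hausdorff distance is an error
  for empty masks.
* "Average Hausdorff" means the symmetric mean over boundary pixels
  (4-neighbour boundary definition, exact Euclidean distance transform);
  the classical maximum variant is available by flag.
* Connected components use 8-connectivity everywhere.
* The post-processing fragment threshold has no universal value (the study
  tied it to the smallest annotated tumor of its cohort); it defaults to
  0.1 % of the mask area and is required configuration for serious use.
* Blank images produce an all-zero tissue mask (no error); an image smaller
  than one tile produces an empty grid with a warning; an undersized crop
  region errors unless padding is requested.
* Probability bounds are preserved through every stage: bilinear stitching
  is convex, the U-Net output is a softmax, and post-processing operates on
  binary masks.

## Known limitations

* The trainable networks are deliberately tiny; the package profiles but
  does not train the full-scale backbones (no pretrained weights are
  shipped or downloadable here).
* The fused model's published parameter total cannot be pinned without the
  unpublished truncation points; the acceptance suite gates the six
  baseline backbones instead, where exact counts are published.
* FLOP estimates follow one stated convention and are not comparable across
  profilers to better than a few percent.
* Fixture realism is limited as described above; conclusions about clinical
  data require clinical data.
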