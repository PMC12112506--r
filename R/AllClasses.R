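#' @import methods
#' @importFrom stats runif rnorm quantile median sd setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## ---------------------------------------------------------------------------
## Augmentation configuration
## ---------------------------------------------------------------------------

#' Multi-lens distortion configuration
#'
#' Parameters of the multi-lens distortion augmentation: a number of lenses
#' are dropped at random positions on the image and each applies a local
#' radial (barrel or pincushion) warp. Positive strength values compress the
#' periphery towards the lens centre (pincushion-like), negative values bulge
#' it outwards (barrel-like); the sign of each draw selects the mode.
#'
#' @slot nLenses integer, number of lenses \eqn{N \ge 0}.
#' @slot radiusRange integer vector \code{c(rmin, rmax)} of lens radii in
#'   pixels, \code{1 <= rmin <= rmax}.
#' @slot strengthRange numeric vector \code{c(smin, smax)} of distortion
#'   strengths, finite, \code{smin <= smax}.
#'
#' @seealso [distortionConfig()], [sampleLenses()], [multiLensDistort()]
#' @export
setClass("DistortionConfig",
  representation(nLenses = "integer",
                 radiusRange = "integer",
                 strengthRange = "numeric"),
  prototype(nLenses = 3L, radiusRange = c(40L, 110L),
            strengthRange = c(-0.4, 0.4)))

setValidity("DistortionConfig", function(object) {
  msg <- character()
  if (length(object@nLenses) != 1L || is.na(object@nLenses) ||
      object@nLenses < 0L)
    msg <- c(msg, "nLenses must be a single non-negative integer")
  if (length(object@radiusRange) != 2L || anyNA(object@radiusRange))
    msg <- c(msg, "radiusRange must be two integers")
  else {
    if (object@radiusRange[1] < 1L)
      msg <- c(msg, "rmin must be >= 1")
    if (object@radiusRange[1] > object@radiusRange[2])
      msg <- c(msg, "radiusRange must be ordered (rmin <= rmax)")
  }
  if (length(object@strengthRange) != 2L ||
      any(!is.finite(object@strengthRange)))
    msg <- c(msg, "strengthRange must be two finite numbers")
  else if (object@strengthRange[1] > object@strengthRange[2])
    msg <- c(msg, "strengthRange must be ordered (smin <= smax)")
  if (length(msg)) msg else TRUE
})

#' Construct a DistortionConfig
#'
#' @param nLenses number of lenses (default 3).
#' @param radiusRange integer radii range in pixels (default \code{c(40, 110)},
#'   sized for 224x224 patches).
#' @param strengthRange strength range (default \code{c(-0.4, 0.4)}, the range
#'   in which the augmentation was found to help rather than distort tissue
#'   morphology beyond recognition).
#' @return A [DistortionConfig-class] object.
#' @examples
#' distortionConfig(nLenses = 2, radiusRange = c(10, 30))
#' @export
distortionConfig <- function(nLenses = 3L, radiusRange = c(40L, 110L),
                             strengthRange = c(-0.4, 0.4)) {
  new("DistortionConfig", nLenses = as.integer(nLenses),
      radiusRange = as.integer(radiusRange),
      strengthRange = as.numeric(strengthRange))
}

setMethod("show", "DistortionConfig", function(object) {
  cat(sprintf("DistortionConfig: N=%d lenses, R in [%d, %d] px, S in [%.3g, %.3g]\n",
              object@nLenses, object@radiusRange[1], object@radiusRange[2],
              object@strengthRange[1], object@strengthRange[2]))
})

#' Standard augmentation configuration
#'
#' Flags and ranges for the stochastic augmentation stack applied to training
#' patches: horizontal/vertical flips, rotations by multiples of 90 degrees,
#' multiplicative contrast, hue shift, brightness shift, and the multi-lens
#' distortion.
#'
#' @slot pFlipH,pFlipV,pRot90,pDistort probabilities in [0,1] of applying each
#'   transform.
#' @slot contrastRange multiplicative contrast factor range (1 = identity).
#' @slot hueShiftRange additive hue shift range, in fraction of the hue circle.
#' @slot brightnessRange additive brightness shift range.
#' @slot distortion a [DistortionConfig-class].
#' @export
setClass("AugmentConfig",
  representation(pFlipH = "numeric", pFlipV = "numeric", pRot90 = "numeric",
                 pDistort = "numeric", contrastRange = "numeric",
                 hueShiftRange = "numeric", brightnessRange = "numeric",
                 distortion = "DistortionConfig"))

setValidity("AugmentConfig", function(object) {
  p <- c(object@pFlipH, object@pFlipV, object@pRot90, object@pDistort)
  msg <- character()
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  for (nm in c("contrastRange", "hueShiftRange", "brightnessRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be an ordered finite pair", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AugmentConfig
#'
#' Defaults give the identity transform with probability-0 flips/rotations and
#' neutral colour ranges; enable pieces explicitly for training.
#'
#' @param pFlipH,pFlipV,pRot90,pDistort application probabilities.
#' @param contrastRange,hueShiftRange,brightnessRange colour jitter ranges.
#' @param distortion a [DistortionConfig-class] used when distortion fires.
#' @return An [AugmentConfig-class] object.
#' @export
augmentConfig <- function(pFlipH = 0.5, pFlipV = 0.5, pRot90 = 0.5,
                          pDistort = 0.5,
                          contrastRange = c(0.9, 1.1),
                          hueShiftRange = c(-0.02, 0.02),
                          brightnessRange = c(-0.05, 0.05),
                          distortion = distortionConfig()) {
  new("AugmentConfig", pFlipH = pFlipH, pFlipV = pFlipV, pRot90 = pRot90,
      pDistort = pDistort, contrastRange = as.numeric(contrastRange),
      hueShiftRange = as.numeric(hueShiftRange),
      brightnessRange = as.numeric(brightnessRange), distortion = distortion)
}

## ---------------------------------------------------------------------------
## Synthetic fixtures
## ---------------------------------------------------------------------------

#' Specification of a synthetic H&E-like fixture
#'
#' Describes a synthetic slide image at desk scale: near-white glass
#' background, textured eosin-pink tissue from thresholded low-pass noise, and
#' smooth hematoxylin-purple tumor blobs. \code{separability} scales the
#' colour/texture shift between tumor and non-tumor tissue, so downstream
#' classification difficulty is controllable.
#'
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @slot imageSize integer edge length in pixels; must be divisible by the
#'   224-pixel tile size and by 1120 (the down-sampled refinement frame).
#' @slot nTumorBlobs integer number of tumor blobs.
#' @slot blobScale numeric blob radius scale in pixels.
#' @slot tissueCoverage numeric target tissue fraction in (0, 1).
#' @slot separability numeric >= 0 tumor vs non-tumor contrast.
#' @slot palette list of RGB triplets (\code{background}, \code{tissue},
#'   \code{tumor}), each in [0,1].
#' @export
setClass("FixtureSpec",
  representation(seed = "integer", imageSize = "integer",
                 nTumorBlobs = "integer", blobScale = "numeric",
                 tissueCoverage = "numeric", separability = "numeric",
                 palette = "list"))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@imageSize < 224L)
    msg <- c(msg, "imageSize must be at least one 224-pixel tile")
  if (object@imageSize %% 224L != 0L || object@imageSize %% 1120L != 0L)
    msg <- c(msg, "imageSize must be divisible by 224 and by 1120")
  if (!is.finite(object@tissueCoverage) || object@tissueCoverage <= 0 ||
      object@tissueCoverage >= 1)
    msg <- c(msg, "tissueCoverage must lie in (0, 1)")
  if (object@nTumorBlobs < 0L)
    msg <- c(msg, "nTumorBlobs must be >= 0")
  if (!is.finite(object@separability) || object@separability < 0)
    msg <- c(msg, "separability must be >= 0")
  if (!all(c("background", "tissue", "tumor") %in% names(object@palette)))
    msg <- c(msg, "palette must name background, tissue and tumor colours")
  if (length(msg)) msg else TRUE
})

#' Construct a FixtureSpec
#'
#' @param seed RNG seed.
#' @param imageSize image edge in pixels; default 4480 so the 1120x1120
#'   down-sample is an integer x4 factor (use 1120 for desk-scale work).
#' @param nTumorBlobs number of tumor blobs (default 3).
#' @param blobScale blob radius scale in pixels; default scales with the
#'   image (image/4.5) so blobs are large enough to carry whole tiles.
#' @param tissueCoverage target tissue fraction (default 0.55).
#' @param separability tumor/non-tumor contrast (default 1; 0 makes tumor
#'   indistinguishable from tissue).
#' @param palette background/tissue/tumor RGB triplets.
#' @return A [FixtureSpec-class].
#' @examples
#' spec <- fixtureSpec(seed = 1, imageSize = 1120)
#' spec
#' @export
fixtureSpec <- function(seed = 1L, imageSize = 4480L, nTumorBlobs = 3L,
                        blobScale = imageSize / 4.5, tissueCoverage = 0.55,
                        separability = 1,
                        palette = list(background = c(0.955, 0.945, 0.965),
                                       tissue = c(0.87, 0.60, 0.72),
                                       tumor = c(0.48, 0.32, 0.58))) {
  new("FixtureSpec", seed = as.integer(seed), imageSize = as.integer(imageSize),
      nTumorBlobs = as.integer(nTumorBlobs), blobScale = as.numeric(blobScale),
      tissueCoverage = as.numeric(tissueCoverage),
      separability = as.numeric(separability), palette = palette)
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(paste0("FixtureSpec: %dx%d px, %d tumor blob(s), ",
                     "coverage %.2f, separability %.2f, seed %d\n"),
              object@imageSize, object@imageSize, object@nTumorBlobs,
              object@tissueCoverage, object@separability, object@seed))
})

#' A generated synthetic fixture
#'
#' Holds the rendered RGB image, the ground-truth tumor and tissue masks,
#' PSA-style labelled rectangular regions (mimicking sparsely annotated
#' regions of interest a pathologist would mark), and a provenance manifest.
#'
#' Invariants enforced by validity: the tumor mask is a subset of the tissue
#' mask; regions lie inside the image; tumor-labelled regions overlap the
#' tumor mask by at least 95 percent and non-tumor regions by exactly 0.
#'
#' @slot image numeric array H x W x 3 in [0,1].
#' @slot tumorMask,tissueMask binary integer matrices H x W.
#' @slot psaRegions data.frame with columns \code{y0, x0, y1, x1}
#'   (1-based inclusive pixel bounds) and \code{label}
#'   (\code{"tumor"}/\code{"non_tumor"}).
#' @slot manifest list with the seed and generation parameters.
#' @export
setClass("FixtureBundle",
  representation(image = "array", tumorMask = "matrix", tissueMask = "matrix",
                 psaRegions = "data.frame", manifest = "list"))

setValidity("FixtureBundle", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!identical(dim(object@tumorMask), d[1:2]) ||
      !identical(dim(object@tissueMask), d[1:2]))
    msg <- c(msg, "masks must match the image plane")
  if (any(object@tumorMask > object@tissueMask))
    msg <- c(msg, "tumorMask must be a subset of tissueMask")
  rg <- object@psaRegions
  if (nrow(rg)) {
    if (any(rg$y0 < 1 | rg$x0 < 1 | rg$y1 > d[1] | rg$x1 > d[2]))
      msg <- c(msg, "psaRegions must lie inside the image")
    for (i in seq_len(nrow(rg))) {
      sub <- object@tumorMask[rg$y0[i]:rg$y1[i], rg$x0[i]:rg$x1[i]]
      ov <- mean(sub)
      if (rg$label[i] == "tumor" && ov < 0.95)
        msg <- c(msg, sprintf("tumor region %d overlaps tumor mask %.2f < 0.95", i, ov))
      if (rg$label[i] == "non_tumor" && ov > 0)
        msg <- c(msg, sprintf("non_tumor region %d overlaps tumor mask", i))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FixtureBundle", function(object) {
  d <- dim(object@image)
  cat(sprintf("FixtureBundle: %dx%d image, tissue %.1f%%, tumor %.1f%%, %d PSA region(s)\n",
              d[1], d[2], 100 * mean(object@tissueMask),
              100 * mean(object@tumorMask), nrow(object@psaRegions)))
})

#' @rdname fixtureAccessors
#' @param object a [FixtureBundle-class]
#' @export
setGeneric("fixtureImage", function(object) standardGeneric("fixtureImage"))
#' @rdname fixtureAccessors
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))
#' @rdname fixtureAccessors
#' @export
setGeneric("tissueMaskOf", function(object) standardGeneric("tissueMaskOf"))
#' @rdname fixtureAccessors
#' @export
setGeneric("psaRegions", function(object) standardGeneric("psaRegions"))

#' Accessors for FixtureBundle slots
#'
#' @name fixtureAccessors
#' @return the image array, binary mask matrices, or region table.
NULL

#' @rdname fixtureAccessors
#' @export
setMethod("fixtureImage", "FixtureBundle", function(object) object@image)
#' @rdname fixtureAccessors
#' @export
setMethod("tumorMask", "FixtureBundle", function(object) object@tumorMask)
#' @rdname fixtureAccessors
#' @export
setMethod("tissueMaskOf", "FixtureBundle", function(object) object@tissueMask)
#' @rdname fixtureAccessors
#' @export
setMethod("psaRegions", "FixtureBundle", function(object) object@psaRegions)

## ---------------------------------------------------------------------------
## Tiling
## ---------------------------------------------------------------------------

#' Tile labelling rules
#'
#' The labelling rules for 224x224 tiles: a tile is kept only if it contains
#' strictly more than \code{minTissue} tissue; a kept tile is labelled tumor
#' when its tumor fraction is at least \code{minTumor}; non-tumor labels
#' require a tumor fraction of exactly zero (when
#' \code{nonTumorRequiresZero}); kept tiles with tumor fraction strictly
#' between zero and \code{minTumor} are excluded from training.
#'
#' @slot minTissue minimum tissue fraction, strict inequality (default 0.25).
#' @slot minTumor minimum tumor fraction for the tumor label, inclusive
#'   (default 0.05).
#' @slot nonTumorRequiresZero logical (default TRUE).
#' @export
setClass("TileRules",
  representation(minTissue = "numeric", minTumor = "numeric",
                 nonTumorRequiresZero = "logical"),
  prototype(minTissue = 0.25, minTumor = 0.05, nonTumorRequiresZero = TRUE))

setValidity("TileRules", function(object) {
  if (object@minTumor < 0 || object@minTissue > 1 ||
      object@minTumor > object@minTissue)
    "rules must satisfy 0 <= minTumor <= minTissue <= 1"
  else TRUE
})

#' Construct TileRules
#' @param minTissue,minTumor,nonTumorRequiresZero see [TileRules-class].
#' @return A [TileRules-class].
#' @export
tileRules <- function(minTissue = 0.25, minTumor = 0.05,
                      nonTumorRequiresZero = TRUE) {
  new("TileRules", minTissue = minTissue, minTumor = minTumor,
      nonTumorRequiresZero = nonTumorRequiresZero)
}

## ---------------------------------------------------------------------------
## Heatmap
## ---------------------------------------------------------------------------

#' Stitched patch-probability heatmap
#'
#' One tumor probability per grid tile; glass/excluded tiles are fixed at 0.
#'
#' @slot probs numeric matrix (grid rows x grid cols) in [0,1].
#' @slot kept logical matrix, TRUE where the tile passed the tissue rule.
#' @slot tileSize,stride integers (pixels).
#' @slot sourceDim integer c(H, W) of the source image.
#' @export
setClass("Heatmap",
  representation(probs = "matrix", kept = "matrix", tileSize = "integer",
                 stride = "integer", sourceDim = "integer"))

setValidity("Heatmap", function(object) {
  msg <- character()
  if (any(object@probs < 0 | object@probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!identical(dim(object@probs), dim(object@kept)))
    msg <- c(msg, "probs and kept must have identical dimensions")
  if (any(object@probs[!object@kept] != 0))
    msg <- c(msg, "excluded cells must hold probability 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap: %dx%d grid (%d kept), tile %d px, source %dx%d\n",
              nrow(object@probs), ncol(object@probs), sum(object@kept),
              object@tileSize, object@sourceDim[1], object@sourceDim[2]))
})

#' @rdname heatmapAccessors
#' @param object a [Heatmap-class]
#' @export
setGeneric("heatmapProbs", function(object) standardGeneric("heatmapProbs"))

#' Accessors for Heatmap
#' @name heatmapAccessors
#' @return the probability grid matrix.
NULL

#' @rdname heatmapAccessors
#' @export
setMethod("heatmapProbs", "Heatmap", function(object) object@probs)

## ---------------------------------------------------------------------------
## Post-processing
## ---------------------------------------------------------------------------

#' Post-processing configuration
#'
#' Order of operations on the binarized segmentation: (1) remove connected
#' components smaller than \code{minFragmentArea}; (2) morphological opening
#' with a square kernel; (3) median blur, then re-binarize.
#'
#' @slot minFragmentArea minimum component area in pixels; components below it
#'   are dropped. The study pinned this to the smallest annotated tumor area
#'   of its ground truth, which is cohort specific; the constructor default is
#'   0.1 percent of the mask area (set at call time when the mask is known).
#' @slot openingKernel odd kernel edge for the opening (default 7).
#' @slot medianKernel odd kernel edge for the median blur (default 11).
#' @slot connectivity pixel connectivity for components (8, fixed).
#' @export
setClass("PostprocessConfig",
  representation(minFragmentArea = "numeric", openingKernel = "integer",
                 medianKernel = "integer", connectivity = "integer"),
  prototype(minFragmentArea = NA_real_, openingKernel = 7L,
            medianKernel = 11L, connectivity = 8L))

setValidity("PostprocessConfig", function(object) {
  msg <- character()
  if (object@openingKernel %% 2L == 0L || object@medianKernel %% 2L == 0L)
    msg <- c(msg, "kernels must be odd")
  if (!is.na(object@minFragmentArea) && object@minFragmentArea < 0)
    msg <- c(msg, "minFragmentArea must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' Construct a PostprocessConfig
#' @param minFragmentArea minimum fragment area in pixels; \code{NA} (default)
#'   resolves to 0.1 percent of the mask area at run time.
#' @param openingKernel,medianKernel odd kernel sizes (defaults 7 and 11).
#' @param connectivity 4 or 8 (default 8).
#' @return A [PostprocessConfig-class].
#' @export
postprocessConfig <- function(minFragmentArea = NA_real_, openingKernel = 7L,
                              medianKernel = 11L, connectivity = 8L) {
  new("PostprocessConfig", minFragmentArea = as.numeric(minFragmentArea),
      openingKernel = as.integer(openingKernel),
      medianKernel = as.integer(medianKernel),
      connectivity = as.integer(connectivity))
}

## ---------------------------------------------------------------------------
## Complexity report
## ---------------------------------------------------------------------------

#' Model complexity report
#'
#' Exact parameter counts and FLOP estimates for a model and a baseline, with
#' relative deltas computed from the unrounded counts:
#' \deqn{\Delta = (x_{model} - x_{baseline}) / x_{baseline} \times 100.}
#' FLOPs count one forward pass of a 224x224x3 input with multiplies and adds
#' counted separately (2 x multiply-accumulates).
#'
#' @slot modelName,baselineName character.
#' @slot flopsModel,flopsBaseline,paramsModel,paramsBaseline raw counts
#'   (operations / parameters, not millions).
#' @slot deltaFlopsPct,deltaParamsPct percentages.
#' @export
setClass("ComplexityReport",
  representation(modelName = "character", baselineName = "character",
                 flopsModel = "numeric", flopsBaseline = "numeric",
                 paramsModel = "numeric", paramsBaseline = "numeric",
                 deltaFlopsPct = "numeric", deltaParamsPct = "numeric"))

setValidity("ComplexityReport", function(object) {
  msg <- character()
  dP <- (object@paramsModel - object@paramsBaseline) /
    object@paramsBaseline * 100
  dF <- (object@flopsModel - object@flopsBaseline) /
    object@flopsBaseline * 100
  if (abs(dP - object@deltaParamsPct) > 1e-9 * max(1, abs(dP)))
    msg <- c(msg, "deltaParamsPct inconsistent with raw counts")
  if (abs(dF - object@deltaFlopsPct) > 1e-9 * max(1, abs(dF)))
    msg <- c(msg, "deltaFlopsPct inconsistent with raw counts")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComplexityReport", function(object) {
  cat(sprintf("ComplexityReport: %s vs baseline %s\n",
              object@modelName, object@baselineName))
  cat(sprintf("  FLOPs  %10.2f M (baseline %10.2f M)  dFLOPs  %8.2f%%\n",
              object@flopsModel / 1e6, object@flopsBaseline / 1e6,
              object@deltaFlopsPct))
  cat(sprintf("  Params %10.2f M (baseline %10.2f M)  dParams %8.2f%%\n",
              object@paramsModel / 1e6, object@paramsBaseline / 1e6,
              object@deltaParamsPct))
})

## ---------------------------------------------------------------------------
## Networks
## ---------------------------------------------------------------------------

#' A network: symbolic layer table, optionally with trainable weights
#'
#' Two flavours share this container. Symbolic networks (the standard
#' ImageNet backbones, the fused patch classifier at full scale, the
#' 1120-pixel refinement U-Net) carry only the exact per-layer shape and
#' parameter/FLOP enumeration used for complexity profiling. Trainable
#' networks (the tiny fused patch classifier and the tiny U-Net used for
#' desk-scale experiments) additionally carry weight arrays and support
#' forward/backward passes.
#'
#' @slot name character model name.
#' @slot kind internal architecture tag ("symbolic", "tinyPWC", "tinyUNet",
#'   "dense", "constant").
#' @slot layers data.frame with columns \code{layer, type, out_h, out_w,
#'   out_c, params, flops}.
#' @slot params named list of weight arrays (empty for symbolic networks).
#' @slot state named list of non-weight state (batch-norm running statistics).
#' @slot config architecture parameters (depth, filters, skip flags, ...).
#' @export
setClass("WsiNetwork",
  representation(name = "character", kind = "character", layers = "data.frame",
                 params = "list", state = "list", config = "list"))

setMethod("show", "WsiNetwork", function(object) {
  cat(sprintf("WsiNetwork '%s' (%s): %d layers, %s parameters%s\n",
              object@name, object@kind, nrow(object@layers),
              format(sum(object@layers$params), big.mark = ","),
              if (length(object@params)) " [trainable]" else " [symbolic]"))
})

#' @rdname networkAccessors
#' @param object a [WsiNetwork-class]
#' @export
setGeneric("networkLayers", function(object) standardGeneric("networkLayers"))
#' @rdname networkAccessors
#' @export
setGeneric("paramCount", function(object) standardGeneric("paramCount"))
#' @rdname networkAccessors
#' @export
setGeneric("flopsCount", function(object) standardGeneric("flopsCount"))

#' Accessors for WsiNetwork
#'
#' \code{paramCount} returns the exact integer-valued parameter count (all
#' weights, including non-trainable batch-norm statistics, matching the
#' convention of framework model summaries); \code{flopsCount} the estimated
#' forward-pass FLOPs (2 x multiply-accumulates).
#'
#' @name networkAccessors
#' @return layer table, parameter count, or FLOP count.
NULL

#' @rdname networkAccessors
#' @export
setMethod("networkLayers", "WsiNetwork", function(object) object@layers)
#' @rdname networkAccessors
#' @export
setMethod("paramCount", "WsiNetwork",
          function(object) sum(object@layers$params))
#' @rdname networkAccessors
#' @export
setMethod("flopsCount", "WsiNetwork",
          function(object) sum(object@layers$flops))
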