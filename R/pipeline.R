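#' Desk-scale end-to-end cascade experiment on synthetic fixtures
#'
#' Reproduces the full two-stage workflow at a size that trains from scratch
#' on one CPU in minutes: (1) a labelled PSA-style region set is generated
#' and the tiny fused patch classifier is trained on random crops with the
#' full augmentation stack (including multi-lens distortion); (2) synthetic
#' slides are generated, the classifier produces per-tile heatmaps which are
#' stitched to the refinement frame; (3) the tiny U-Net is trained on
#' (RGB + heatmap, mask) pairs with Dice loss; (4) held-out slides are
#' scored: Dice of the refined segmentation and of the thresholded
#' heatmap-only baseline against the generator's ground truth, both at the
#' refinement frame.
#'
#' @param seed master seed; all sub-streams (region set, weights, crops,
#'   fixtures, splits) derive from it.
#' @param imageSize fixture edge (default 1120: a 5x5 tile grid).
#' @param separability tumor/non-tumor contrast of the fixtures (default 1,
#'   the clearly separable regime sparse annotation is designed for).
#' @param counts tumor/non-tumor region counts for classifier training
#'   (default \code{c(40, 50)}, the deliberately imbalanced design).
#' @param nTrainFixtures slides for U-Net training+validation (default 8).
#' @param nTestFixtures held-out slides (default 3).
#' @param refineSize refinement frame (default 140; divisible by the tiny
#'   U-Net's pooling factor).
#' @param pwcConfig,unetConfig training configurations; the defaults shrink
#'   the epoch caps to desk scale and raise the learning rate to suit the
#'   tiny networks.
#' @param augment augmentation stack for classifier training.
#' @return list with \code{scores} (per test fixture: dscRefined,
#'   dscHeatmap), \code{meanDscRefined}, \code{meanDscHeatmap}, \code{pwc},
#'   \code{unet}, \code{pwcHistory}, \code{unetHistory}.
#' @export
runCascadeExperiment <- function(seed = 1L, imageSize = 1120L,
                                 separability = 1, counts = c(40L, 50L),
                                 nTrainFixtures = 8L, nTestFixtures = 3L,
                                 refineSize = 140L,
                                 pwcConfig = pwcTrainConfig(
                                   lr = 1e-2, maxEpochs = 12L,
                                   patience = 6L, batchSize = 8L),
                                 unetConfig = unetTrainConfig(
                                   lr = 3e-3, maxEpochs = 30L,
                                   patience = 10L),
                                 augment = augmentConfig()) {
  ## stage 1: classifier on PSA-style regions
  ps <- generatePatchSet(
    fixtureSpec(seed = deriveSeed(seed, 1L), imageSize = imageSize,
                separability = separability),
    counts = counts)
  pwcNet <- tinyPWC(seed = deriveSeed(seed, 2L))
  pwcFit <- trainPWC(pwcNet, ps, pwcConfig, seed = deriveSeed(seed, 3L),
                     augment = augment)

  ## stage 2: heatmaps over synthetic slides -> refinement pairs
  nFix <- nTrainFixtures + nTestFixtures
  pairs <- vector("list", nFix)
  stitchedMaps <- vector("list", nFix)
  for (i in seq_len(nFix)) {
    b <- suppressWarnings(generateFixture(
      fixtureSpec(seed = deriveSeed(seed, 100L + i), imageSize = imageSize,
                  separability = separability)))
    hm <- predictHeatmap(pwcFit$net, b@image)
    st <- stitchAndResize(hm, refineSize)
    rgbS <- downsampleImage(b@image, refineSize)
    y <- downsampleImage(b@tumorMask, refineSize, binarize = 0.5)
    pairs[[i]] <- list(x = array(c(rgbS, st), c(refineSize, refineSize, 4L)),
                       y = y)
    stitchedMaps[[i]] <- st
  }
  trainIdx <- seq_len(nTrainFixtures)
  testIdx <- nTrainFixtures + seq_len(nTestFixtures)

  unetNet <- tinyUNet(inputSize = refineSize, seed = deriveSeed(seed, 4L))
  unetFit <- trainRefinement(unetNet, pairs[trainIdx], unetConfig,
                             seed = deriveSeed(seed, 5L))

  ## stage 3: held-out evaluation
  scores <- do.call(rbind, lapply(testIdx, function(i) {
    refined <- unetForward(unetFit$net, pairs[[i]]$x)$probs[, , 2L]
    data.frame(fixture = i,
               dscRefined = diceScore((refined >= 0.5) + 0, pairs[[i]]$y),
               dscHeatmap = diceScore((stitchedMaps[[i]] >= 0.5) + 0,
                                      pairs[[i]]$y))
  }))
  list(scores = scores,
       meanDscRefined = mean(scores$dscRefined),
       meanDscHeatmap = mean(scores$dscHeatmap),
       pwc = pwcFit$net, unet = unetFit$net,
       pwcHistory = pwcFit$history, unetHistory = unetFit$history)
}
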