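#' Predict the patch-probability heatmap of an image
#'
#' Applies the patch classifier to every grid tile that passes the tissue
#' rule (strictly more than \code{minTissue} tissue). Glass and excluded
#' tiles are fixed at probability 0.
#'
#' @param net classifier network (trainable or constant stub).
#' @param image RGB array H x W x 3.
#' @param tileSize tile edge (default 224).
#' @param rules a [TileRules-class]; only the tissue rule is used here.
#' @param tissue optional precomputed binary tissue mask; default runs
#'   [tissueMask()].
#' @return a [Heatmap-class].
#' @export
predictHeatmap <- function(net, image, tileSize = 224L, rules = tileRules(),
                           tissue = NULL) {
  if (is.null(tissue)) tissue <- tissueMask(image)
  grid <- tileGrid(nrow(tissue), ncol(tissue), tileSize)
  nr <- max(grid$row) + 1L; nc <- max(grid$col) + 1L
  probs <- matrix(0, nr, nc); kept <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ys <- (g$y0 + 1L):(g$y0 + tileSize); xs <- (g$x0 + 1L):(g$x0 + tileSize)
    if (mean(tissue[ys, xs]) > rules@minTissue) {
      kept[g$row + 1L, g$col + 1L] <- TRUE
      probs[g$row + 1L, g$col + 1L] <-
        predictPatchProb(net, image[ys, xs, , drop = FALSE])
    }
  }
  new("Heatmap", probs = probs, kept = kept, tileSize = as.integer(tileSize),
      stride = as.integer(tileSize),
      sourceDim = c(nrow(tissue), ncol(tissue)))
}

#' Stitch a heatmap to a target frame
#'
#' Resizes the per-tile probability grid to \code{target x target} pixels by
#' bilinear interpolation (nearest-neighbour by flag). Bilinear weights are
#' convex, so values stay within the input range; the output is additionally
#' clamped to [0,1] against floating-point drift.
#'
#' @param hm a [Heatmap-class].
#' @param target output edge in pixels (default 1120).
#' @param nearest use nearest-neighbour instead of bilinear.
#' @return numeric target x target matrix in [0, 1].
#' @export
stitchAndResize <- function(hm, target = 1120L, nearest = FALSE) {
  if (!nrow(hm@probs)) stop("empty heatmap")
  clampNum(resizeHW(hm@probs, target, target, nearest = nearest), 0, 1)
}

#' Refine a heatmap with the U-Net
#'
#' Concatenates the down-sampled RGB image and the stitched heatmap into a
#' 4-channel input and runs the refinement network; returns the tumor
#' channel of the per-pixel softmax.
#'
#' @param net a trainable U-Net ([tinyUNet()]).
#' @param rgb H x W x 3 array (down-sampled slide).
#' @param heat H x W heatmap matrix.
#' @return H x W matrix of tumor probabilities.
#' @export
refineHeatmap <- function(net, rgb, heat) {
  if (!identical(dim(rgb)[1:2], dim(heat)))
    stop("rgb and heatmap shapes differ")
  x <- array(c(rgb, heat), c(dim(heat), 4L))
  unetForward(net, x)$probs[, , 2L]
}

## 8-connected component labelling: 4-connected pass, then union of labels
## touching diagonally
labelComponents8 <- function(m) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(m != 0) + 0))))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  a <- lab[-H, -W]; b <- lab[-1, -1]
  c2 <- lab[-1, -W]; d2 <- lab[-H, -1]
  prs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
               cbind(c2[c2 > 0 & d2 > 0 & c2 != d2],
                     d2[c2 > 0 & d2 > 0 & c2 != d2]))
  if (nrow(prs)) {
    for (r in seq_len(nrow(prs))) {
      ra <- findRoot(prs[r, 1]); rb <- findRoot(prs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), findRoot, 0L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Post-process a binary segmentation mask
#'
#' Pipeline order: (1) connected components (8-connectivity) smaller than
#' \code{minFragmentArea} pixels are removed; (2) morphological opening with
#' a square \code{openingKernel} brush smooths jagged edges; (3) a median
#' blur with a square \code{medianKernel} window further smooths boundaries,
#' after which the near-binary result is re-binarized at 0.5.
#'
#' @param mask binary H x W matrix.
#' @param config a [postprocessConfig()]; an \code{NA} fragment threshold
#'   resolves to 0.1 percent of the mask area.
#' @return binary H x W matrix (0/1 integers).
#' @export
postprocessMask <- function(mask, config = postprocessConfig()) {
  m <- (mask != 0) + 0
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  minArea <- config@minFragmentArea
  if (is.na(minArea)) minArea <- 0.001 * length(m)
  if (minArea > 0) {
    lab <- labelComponents8(m)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= minArea)
    m <- (lab %in% keep) + 0
    dim(m) <- dim(mask)
  }
  if (any(m > 0)) {
    brush <- EBImage::makeBrush(config@openingKernel, "box")
    m <- t(EBImage::opening(EBImage::Image(t(m)), brush))
  }
  if (any(m > 0)) {
    half <- (config@medianKernel - 1L) %/% 2L
    m <- t(EBImage::medianFilter(EBImage::Image(t(m)), half))
    m <- (m > 0.5) + 0
  }
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}

#' Down-sample an RGB image or mask to a square frame
#'
#' @param img H x W x 3 array or H x W matrix.
#' @param size target edge in pixels.
#' @param binarize threshold applied after resizing masks (default NULL:
#'   no thresholding).
#' @return resized array/matrix.
#' @export
downsampleImage <- function(img, size, binarize = NULL) {
  if (is.matrix(img)) {
    out <- resizeHW(img, size, size)
    if (!is.null(binarize)) out <- (out > binarize) + 0L
    return(out)
  }
  out <- array(0, c(size, size, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- resizeHW(img[, , ch], size, size)
  out
}

#' Segment a slide image end to end
#'
#' Runs the full cascade: tissue detection, patch-probability heatmap,
#' stitching to the refinement frame, U-Net refinement, thresholding at 0.5
#' (equivalent to arg-max for two classes) and post-processing. All
#' intermediates are returned.
#'
#' @param image RGB array.
#' @param pwc patch classifier network.
#' @param unet refinement U-Net (its input size sets the refinement frame).
#' @param rules a [TileRules-class].
#' @param ppConfig a [postprocessConfig()].
#' @param threshold binarization threshold (default 0.5).
#' @param tileSize tile edge (default 224).
#' @return list with \code{tissue}, \code{heatmap} ([Heatmap-class]),
#'   \code{stitched}, \code{refined} (probability matrices),
#'   \code{mask} (thresholded refined), \code{post} (post-processed mask)
#'   and \code{maskHeatmapOnly} (thresholded stitched heatmap, the
#'   classifier-only baseline).
#' @export
segmentWSI <- function(image, pwc, unet, rules = tileRules(),
                       ppConfig = postprocessConfig(), threshold = 0.5,
                       tileSize = 224L) {
  tissue <- tissueMask(image)
  hm <- predictHeatmap(pwc, image, tileSize, rules, tissue)
  frame <- unet@config$inputSize
  stitched <- stitchAndResize(hm, frame)
  rgbSmall <- downsampleImage(image, frame)
  refined <- refineHeatmap(unet, rgbSmall, stitched)
  mask <- (refined >= threshold) + 0L
  list(tissue = tissue, heatmap = hm, stitched = stitched,
       refined = refined, mask = mask,
       post = postprocessMask(mask, ppConfig),
       maskHeatmapOnly = (stitched >= threshold) + 0L)
}
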