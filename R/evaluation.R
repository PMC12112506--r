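checkMasks <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)}. Two empty masks agree perfectly and
#' score 1; one empty mask against a non-empty one scores 0.
#'
#' @param a,b binary masks of identical shape.
#' @return numeric in [0, 1].
#' @examples
#' m <- matrix(0, 4, 4); m2 <- m
#' m[1, 1:4] <- 1; m2[1, 1:2] <- 1
#' diceScore(m, m2)  # 2*2 / (4+2)
#' @export
diceScore <- function(a, b) {
  checkMasks(a, b)
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Intersection over union
#'
#' \eqn{IoU = |A \cap B| / |A \cup B|}; both-empty is defined as 1.
#'
#' @inheritParams diceScore
#' @return numeric in [0, 1].
#' @export
iouScore <- function(a, b) {
  checkMasks(a, b)
  un <- sum(a != 0 | b != 0)
  if (un == 0) return(1)
  sum(a != 0 & b != 0) / un
}

## boundary pixels: mask pixels with at least one 4-neighbour outside the mask
## (image border counts as outside)
maskBoundary <- function(m) {
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -W, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

#' Symmetric average Hausdorff distance between mask boundaries
#'
#' The mean over boundary pixels of A of the Euclidean distance to the
#' nearest boundary pixel of B is averaged with the reverse direction.
#' Computed with an exact Euclidean distance transform. The classical
#' maximum Hausdorff distance is available with \code{kind = "max"}.
#'
#' @param a,b non-empty binary masks of identical shape.
#' @param kind "avg" (default) or "max".
#' @return distance in pixels (>= 0).
#' @export
hausdorffDistance <- function(a, b, kind = c("avg", "max")) {
  kind <- match.arg(kind)
  checkMasks(a, b)
  if (!any(a != 0) || !any(b != 0))
    stop("Hausdorff distance is undefined for an empty mask")
  ba <- maskBoundary(a); bb <- maskBoundary(b)
  ## distance of every pixel to the nearest boundary pixel of the other mask
  dToB <- t(EBImage::distmap(t(1 - (bb + 0)), metric = "euclidean"))
  dToA <- t(EBImage::distmap(t(1 - (ba + 0)), metric = "euclidean"))
  if (kind == "avg") (mean(dToB[ba]) + mean(dToA[bb])) / 2
  else max(max(dToB[ba]), max(dToA[bb]))
}

#' @rdname hausdorffDistance
#' @export
hausdorffAvg <- function(a, b) hausdorffDistance(a, b, "avg")

#' Precision, recall and F1 for patch-wise classification
#'
#' Standard definitions on the tumor (positive) class. Zero-division cases
#' are reported as 0 with a \code{degenerate} flag rather than NaN.
#'
#' @param labels,predictions binary vectors of equal length.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{degenerate}.
#' @examples
#' patchPRF1(c(1,1,0,0), c(1,0,1,0))
#' @export
patchPRF1 <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' Segmentation scores for one mask pair
#'
#' @param pred,truth binary masks.
#' @return data.frame with \code{dsc}, \code{iou}, \code{hd_avg} (NA when
#'   either mask is empty).
#' @export
segScores <- function(pred, truth) {
  hd <- if (any(pred != 0) && any(truth != 0))
    hausdorffAvg(pred, truth) else NA_real_
  data.frame(dsc = diceScore(pred, truth), iou = iouScore(pred, truth),
             hd_avg = hd)
}

#' Evaluate a directory of predictions against ground truth
#'
#' Masks are paired by file name; any unpaired file is an error. Per-image
#' Dice, IoU and average Hausdorff distance are reported together with the
#' unweighted mean and median across images.
#'
#' @param predDir,truthDir directories of mask images (PNG/TIFF).
#' @param out optional CSV path for the per-image report.
#' @return list with \code{perImage} (data.frame, one row per pair) and
#'   \code{aggregate} (mean and median per metric).
#' @export
evaluateRun <- function(predDir, truthDir, out = NULL) {
  pf <- sort(list.files(predDir)); tf <- sort(list.files(truthDir))
  unpaired <- c(setdiff(pf, tf), setdiff(tf, pf))
  if (length(unpaired))
    stop("unpaired mask files: ", paste(unpaired, collapse = ", "))
  readMask <- function(path) {
    m <- readImageHWC(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # RGB-encoded masks
    (m > 0.5) + 0
  }
  rows <- lapply(pf, function(f) {
    cbind(data.frame(file = f),
          segScores(readMask(file.path(predDir, f)),
                    readMask(file.path(truthDir, f))))
  })
  perImage <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("dsc", "iou", "hd_avg"),
    mean = c(mean(perImage$dsc), mean(perImage$iou),
             mean(perImage$hd_avg, na.rm = TRUE)),
    median = c(median(perImage$dsc), median(perImage$iou),
               median(perImage$hd_avg, na.rm = TRUE)))
  if (!is.null(out)) write.csv(perImage, out, row.names = FALSE)
  list(perImage = perImage, aggregate = agg)
}

#' Qualitative segmentation score
#'
#' Encodes the 0-5 expert scoring rubric for visual assessment of a
#' segmentation as an ordered factor with the rubric text attached.
#'
#' @param value integer in 0..5.
#' @return ordered factor of length 1 with a \code{description} attribute.
#' @examples
#' qualScore(4)
#' @export
qualScore <- function(value) {
  descriptions <- c(
    "0" = "No tumor tissue in image or segmentation, or image not suitable for analysis",
    "1" = "Completely wrong segmentation of tumor, tumor tissue not segmented",
    "2" = "A large part of the tumor is not segmented",
    "3" = "Most of the tumor is correctly segmented, but some false positive or false negative areas",
    "4" = "Most of the tumor is correctly segmented, only sparse false positive or false negative areas",
    "5" = "The whole or almost the whole tumor correctly segmented")
  if (length(value) != 1L || is.na(value) || value %% 1 != 0 ||
      value < 0 || value > 5)
    stop("qualitative score must be a single integer in 0..5")
  out <- factor(as.character(value), levels = as.character(0:5),
                ordered = TRUE)
  attr(out, "description") <- unname(descriptions[as.character(value)])
  out
}
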