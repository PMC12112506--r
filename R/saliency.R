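#' Gradient-based saliency map for a patch classifier
#'
#' Computes the gradient of the chosen class score with respect to every
#' input pixel, takes the absolute value, reduces over colour channels by
#' the maximum, and min-max normalizes to [0, 1]. An all-zero gradient
#' (e.g. a model whose output ignores the input) yields an all-zero map via
#' the normalization guard rather than NaN.
#'
#' @param net a differentiable [WsiNetwork-class] ("tinyPWC" or "dense"
#'   kinds); stub models raise an error.
#' @param patch input array H x W x C.
#' @param classIndex 1 = non-tumor, 2 = tumor (default 2).
#' @return numeric H x W matrix in [0, 1].
#' @export
saliencyMap <- function(net, patch, classIndex = 2L) {
  dlogits <- c(0, 0); dlogits[classIndex] <- 1
  dx <- switch(net@kind,
    tinyPWC = {
      fw <- pwcForward(net, patch)
      pwcBackward(net, fw$cache, dlogits)$dx
    },
    dense = {
      g <- net@params$W[, classIndex]
      array(g, dim(patch))
    },
    stop("saliency requires a differentiable model; kind '", net@kind,
         "' is not"))
  m <- apply(abs(dx), c(1, 2), max)
  rng <- range(m)
  if (rng[2] - rng[1] < 1e-20) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Overlay a saliency map on its patch
#'
#' Blends the map into the red channel for quick visual inspection.
#'
#' @param patch H x W x 3 array.
#' @param sal H x W saliency matrix in [0, 1].
#' @param alpha blend weight of the map (default 0.5).
#' @param path optional output image path.
#' @return RGB array (written to \code{path} if given).
#' @export
saliencyOverlay <- function(patch, sal, alpha = 0.5, path = NULL) {
  out <- patch
  out[, , 1] <- clampNum((1 - alpha) * patch[, , 1] + alpha * sal, 0, 1)
  out[, , 2] <- (1 - alpha) * patch[, , 2]
  out[, , 3] <- (1 - alpha) * patch[, , 3]
  if (!is.null(path)) writeImageHWC(out, path)
  out
}
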