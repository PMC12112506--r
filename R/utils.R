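## Internal helpers: image array conventions and I/O.
##
## Throughout the package images are plain numeric arrays indexed [y, x, c]
## (H x W x C, values in [0,1]) and masks are H x W matrices of 0/1.
## EBImage stores images [x, y, c]; the two helpers below convert at the
## boundary. Symmetric filters (gaussian, square morphology, median,
## distance map) are orientation-agnostic and are applied to H x W matrices
## directly.

asEBImage <- function(arr) {
  if (length(dim(arr)) == 2L)
    EBImage::Image(t(arr))
  else
    EBImage::Image(aperm(arr, c(2L, 1L, 3L)), colormode = "Color")
}

fromEBImage <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Read an RGB image or mask from PNG/TIFF
#'
#' @param path file path.
#' @return numeric array H x W x 3 in [0,1] for colour images, or an H x W
#'   matrix for single-channel images.
#' @export
readImageHWC <- function(path) {
  img <- EBImage::readImage(path)
  a <- fromEBImage(img)
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
  if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3]
  a
}

#' Write an image array or mask to PNG/TIFF
#'
#' Masks (H x W 0/1 matrices) are written as single-channel images with
#' values 0/255 in PNG terms; probability maps keep their [0,1] scale.
#'
#' @param x image array H x W x 3 or matrix H x W.
#' @param path destination; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
writeImageHWC <- function(x, path) {
  EBImage::writeImage(asEBImage(x), path)
  invisible(path)
}

## clamp to [lo, hi]
clampNum <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## resize an H x W matrix (bilinear); EBImage's first dimension is our rows
resizeHW <- function(m, H, W, nearest = FALSE) {
  filt <- if (nearest) "none" else "bilinear"
  t(EBImage::resize(EBImage::Image(t(m)), w = W, h = H, filter = filt))
}

## run expr under a local RNG seed without disturbing the caller's stream;
## seed = NULL uses (and advances) the caller's stream
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## derive a child seed (< 2^31) from a base seed and a stream label
deriveSeed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629 + 1
}
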