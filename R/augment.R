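## HSV helpers, vectorized over pixels (h, s, v in [0,1])
rgbToHsv <- function(r, g, b) {
  m <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  list(h = m[1, ], s = m[2, ], v = m[3, ])
}

hsvToRgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

rot90cw <- function(img, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    img <- if (length(dim(img)) == 3L)
      aperm(img, c(2L, 1L, 3L))[, dim(img)[1]:1, , drop = FALSE]
    else t(img)[, dim(img)[1]:1, drop = FALSE]
  }
  img
}

#' Apply the standard stochastic augmentation stack
#'
#' In fixed order: horizontal flip, vertical flip, rotation by a random
#' multiple of 90 degrees, multiplicative contrast about mid-grey
#' (\code{(x - 0.5) * f + 0.5}), hue shift (HSV hue channel, wrapped),
#' additive brightness, then multi-lens distortion. Each transform fires
#' with its configured probability; colour results are clipped to [0, 1].
#' Flips and right-angle rotations are exact pixel permutations.
#'
#' @param img numeric array H x W x 3 in [0,1].
#' @param config an [AugmentConfig-class].
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return augmented image, same shape as input.
#' @examples
#' img <- array(runif(48 * 48 * 3), c(48, 48, 3))
#' identical(standardAugment(img, augmentConfig(0, 0, 0, 0)), img)
#' @export
standardAugment <- function(img, config = augmentConfig(), seed = NULL) {
  stopifnot(is(config, "AugmentConfig"), length(dim(img)) == 3L)
  validObject(config)
  withLocalSeed(seed, {
    if (runif(1) < config@pFlipH) img <- img[, dim(img)[2]:1, , drop = FALSE]
    if (runif(1) < config@pFlipV) img <- img[dim(img)[1]:1, , , drop = FALSE]
    if (runif(1) < config@pRot90) img <- rot90cw(img, sample.int(3L, 1L))
    f <- runif(1, config@contrastRange[1], config@contrastRange[2])
    if (f != 1) img <- clampNum((img - 0.5) * f + 0.5, 0, 1)
    hshift <- runif(1, config@hueShiftRange[1], config@hueShiftRange[2])
    if (hshift != 0) {
      d <- dim(img)
      hsv <- rgbToHsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                      as.vector(img[, , 3]))
      rgb <- hsvToRgb(hsv$h + hshift, hsv$s, hsv$v)
      img <- array(c(rgb$r, rgb$g, rgb$b), d)
    }
    bshift <- runif(1, config@brightnessRange[1], config@brightnessRange[2])
    if (bshift != 0) img <- clampNum(img + bshift, 0, 1)
    if (runif(1) < config@pDistort) {
      d <- dim(img)
      img <- multiLensDistort(img,
        sampleLenses(config@distortion, d[1], d[2], seed = NULL))
    }
    img
  })
}

#' Crop a random square patch from a region image
#'
#' Used to realise "one random crop per region per epoch": a region image
#' yields exactly one \code{size x size} crop with a uniformly drawn offset.
#'
#' @param img array H x W x C or matrix, with both spatial dims >=
#'   \code{size} unless \code{pad = TRUE}.
#' @param size crop edge in pixels (default 224).
#' @param seed optional seed.
#' @param pad if TRUE, undersized regions are zero-padded (with a warning)
#'   instead of raising an error.
#' @return the cropped patch.
#' @export
randomCrop <- function(img, size = 224L, seed = NULL, pad = FALSE) {
  isMat <- is.matrix(img)
  if (isMat) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  if (d[1] < size || d[2] < size) {
    if (!pad) stop(sprintf("region %dx%d smaller than crop size %d",
                           d[1], d[2], size))
    warning("region smaller than crop size; zero-padding")
    padded <- array(0, c(max(d[1], size), max(d[2], size), d[3]))
    padded[seq_len(d[1]), seq_len(d[2]), ] <- img
    img <- padded; d <- dim(img)
  }
  withLocalSeed(seed, {
    y0 <- sample.int(d[1] - size + 1L, 1L)
    x0 <- sample.int(d[2] - size + 1L, 1L)
    out <- img[y0:(y0 + size - 1L), x0:(x0 + size - 1L), , drop = FALSE]
    if (isMat) dim(out) <- c(size, size)
    out
  })
}
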