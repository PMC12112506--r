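#' Sample lens draws for the multi-lens distortion
#'
#' Draws \code{N} lenses for an \code{H x W} image. Per lens the draw order
#' is fixed as (cx, cy, R, S): centre x uniform on \{0, ..., W-1\}, centre y
#' uniform on \{0, ..., H-1\}, integer radius uniform on \{rmin, ..., rmax\},
#' real strength uniform on [smin, smax]. A single RNG stream in this fixed
#' order means one seed pins the whole augmentation.
#'
#' @param config a [DistortionConfig-class].
#' @param H,W image dimensions in pixels (>= 1).
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return data.frame with one row per lens and columns \code{cx, cy}
#'   (0-based integer centres), \code{R} (integer radius), \code{S} (real
#'   strength).
#' @examples
#' sampleLenses(distortionConfig(nLenses = 2, radiusRange = c(5, 20)),
#'              H = 64, W = 64, seed = 7)
#' @export
sampleLenses <- function(config, H, W, seed = NULL) {
  stopifnot(is(config, "DistortionConfig"), H >= 1, W >= 1)
  validObject(config)
  if (config@radiusRange[2] >= min(H, W))
    warning("rmax >= min(H, W): lenses may exceed the image")
  withLocalSeed(seed, {
    n <- config@nLenses
    out <- data.frame(cx = integer(n), cy = integer(n),
                      R = integer(n), S = numeric(n))
    rmin <- config@radiusRange[1]; rmax <- config@radiusRange[2]
    for (i in seq_len(n)) {
      out$cx[i] <- sample.int(W, 1L) - 1L
      out$cy[i] <- sample.int(H, 1L) - 1L
      out$R[i]  <- rmin + sample.int(rmax - rmin + 1L, 1L) - 1L
      out$S[i]  <- runif(1L, config@strengthRange[1], config@strengthRange[2])
    }
    out
  })
}

#' Apply multi-lens distortion to an image
#'
#' Each lens applies a local radial warp inside its disk of radius \code{R}
#' around centre \code{(cx, cy)}: a pixel at distance \code{r < R} is filled
#' from the source position
#' \code{(cx + dx * scale, cy + dy * scale)} with
#' \code{scale = 1 - S * (1 - r/R)}, clamped to the image and gathered by
#' nearest-neighbour (no interpolation; the real-valued source coordinate is
#' truncated toward zero after clamping). Positive \code{S} magnifies the
#' neighbourhood of the centre (pincushion-like at the rim), negative
#' \code{S} shrinks it (barrel-like).
#'
#' Every lens reads from the \emph{original} image, never from the running
#' output, so where disks overlap, later lenses overwrite earlier ones.
#' Pixels outside all disks, and each lens centre pixel itself (r = 0), are
#' unchanged.
#'
#' @param img numeric array H x W x C (C >= 1) or H x W matrix.
#' @param lenses data.frame as returned by [sampleLenses()].
#' @return distorted image with the shape and storage mode of \code{img}.
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' lens <- data.frame(cx = 16, cy = 16, R = 10, S = 0.4)
#' out <- multiLensDistort(img, lens)
#' stopifnot(identical(dim(out), dim(img)))
#' @export
multiLensDistort <- function(img, lenses) {
  isMat <- is.matrix(img)
  if (isMat) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  if (length(d) != 3L || any(d < 1L)) stop("img must be H x W x C, non-empty")
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(all(c("cx", "cy", "R", "S") %in% names(lenses)))
  if (nrow(lenses) &&
      (any(lenses$cx < 0 | lenses$cx >= W | lenses$cy < 0 | lenses$cy >= H) ||
       any(lenses$R < 1)))
    stop("lens centres must lie inside the image and radii must be >= 1")

  out <- img
  if (nrow(lenses) == 0L) { if (isMat) dim(out) <- c(H, W); return(out) }

  ## 0-based pixel coordinate planes (column-major: y varies fastest)
  ys <- rep.int(0:(H - 1L), W)
  xs <- rep(0:(W - 1L), each = H)
  planeLen <- H * W

  for (i in seq_len(nrow(lenses))) {
    cx <- lenses$cx[i]; cy <- lenses$cy[i]
    R <- lenses$R[i]; S <- lenses$S[i]
    dx <- xs - cx; dy <- ys - cy
    r <- sqrt(dx * dx + dy * dy)
    inside <- which(r < R)
    if (!length(inside)) next
    scale <- 1 - S * (1 - r[inside] / R)
    xnew <- clampNum(cx + dx[inside] * scale, 0, W - 1)
    ynew <- clampNum(cy + dy[inside] * scale, 0, H - 1)
    src <- trunc(xnew) * H + trunc(ynew) + 1  # 1-based linear plane index
    for (ch in seq_len(C)) {
      off <- (ch - 1L) * planeLen
      out[inside + off] <- img[src + off]
    }
  }
  if (isMat) dim(out) <- c(H, W)
  out
}

#' Seeded convenience wrapper: sample lenses and distort in one call
#'
#' @param img image array.
#' @param config a [DistortionConfig-class].
#' @param seed optional seed forwarded to [sampleLenses()].
#' @return distorted image.
#' @export
distortImage <- function(img, config = distortionConfig(), seed = NULL) {
  d <- dim(img)
  multiLensDistort(img, sampleLenses(config, d[1], d[2], seed = seed))
}
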