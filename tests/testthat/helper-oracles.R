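## Literal per-pixel reference implementation of the multi-lens distortion:
## a direct double loop over pixels, 0-based coordinates, clamp then integer
## truncation, reading from the original image. Deliberately independent of
## the vectorized production path.
refMultiLens <- function(img, lenses) {
  d <- dim(img); H <- d[1]; W <- d[2]
  out <- img
  for (i in seq_len(nrow(lenses))) {
    cx <- lenses$cx[i]; cy <- lenses$cy[i]
    R <- lenses$R[i]; S <- lenses$S[i]
    for (y in 0:(H - 1)) for (x in 0:(W - 1)) {
      dx <- x - cx; dy <- y - cy
      r <- sqrt(dx * dx + dy * dy)
      if (r < R) {
        scale <- 1 - S * (1 - r / R)
        xn <- min(max(cx + dx * scale, 0), W - 1)
        yn <- min(max(cy + dy * scale, 0), H - 1)
        out[y + 1, x + 1, ] <- img[trunc(yn) + 1, trunc(xn) + 1, ]
      }
    }
  }
  out
}

## shared expensive fixtures, built once per test run
.shared <- new.env()

sharedFixture <- function() {
  if (is.null(.shared$fx))
    .shared$fx <- suppressWarnings(
      generateFixture(fixtureSpec(seed = 7, imageSize = 1120)))
  .shared$fx
}

sharedPatchSet <- function() {
  if (is.null(.shared$ps))
    .shared$ps <- suppressWarnings(generatePatchSet(
      fixtureSpec(seed = 5, imageSize = 1120), counts = c(4L, 5L)))
  .shared$ps
}

randomMask <- function(H, W, p = 0.4) matrix(rbinom(H * W, 1, p), H, W)
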