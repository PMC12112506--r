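#' Detect tissue against the background glass
#'
#' Tissue is separated from glass by a threshold on colour gradients: the
#' gradient magnitude of the grey-level image (central differences) is
#' smoothed, thresholded (Otsu by default, or a fixed value), and the result
#' is morphologically closed and hole-filled so that smooth tissue interiors
#' are retained.
#'
#' @param img RGB array H x W x 3 or grey matrix.
#' @param threshold numeric fixed threshold on the smoothed gradient
#'   magnitude, or \code{"otsu"} (default).
#' @param sigma Gaussian smoothing of the gradient magnitude (default 3 px).
#' @param closeKernel edge of the closing brush (default 9 px).
#' @return binary H x W matrix (1 = tissue, 0 = glass). A blank image gives
#'   an all-zero mask.
#' @export
tissueMask <- function(img, threshold = "otsu", sigma = 3, closeKernel = 9L) {
  g <- if (length(dim(img)) == 3L)
    (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
  H <- nrow(g); W <- ncol(g)
  gy <- matrix(0, H, W); gx <- matrix(0, H, W)
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mag <- EBImage::gblur(mag, sigma = sigma)
  if (identical(threshold, "otsu")) {
    if (max(mag) < 1e-8) return(matrix(0L, H, W))  # blank: no gradients
    threshold <- EBImage::otsu(EBImage::Image(mag / max(mag))) * max(mag)
  }
  bw <- mag > threshold
  if (!any(bw)) return(matrix(0L, H, W))
  brush <- EBImage::makeBrush(closeKernel, "disc")
  bw <- EBImage::closing(EBImage::Image(bw + 0), brush)
  bw <- EBImage::fillHull(bw)
  matrix(as.integer(bw > 0.5), H, W)
}

#' Build the non-overlapping tile grid
#'
#' Row-major grid of \code{size x size} tiles with stride equal to the tile
#' size; ragged margins are dropped. Coordinates are 0-based with half-open
#' bounds \code{[y0, y0 + size) x [x0, x0 + size)}.
#'
#' @param H,W image dimensions.
#' @param size tile edge (default 224).
#' @param stride grid stride (default \code{size}; no overlap).
#' @return data.frame with \code{row, col, y0, x0, size}; zero rows (with a
#'   warning) when the image is smaller than one tile.
#' @examples
#' nrow(tileGrid(448, 448))  # 4
#' @export
tileGrid <- function(H, W, size = 224L, stride = size) {
  size <- as.integer(size); stride <- as.integer(stride)
  nr <- (H - size) %/% stride + 1L
  nc <- (W - size) %/% stride + 1L
  if (H < size || W < size) {
    warning("image smaller than one tile; empty grid")
    return(data.frame(row = integer(0), col = integer(0), y0 = integer(0),
                      x0 = integer(0), size = integer(0)))
  }
  g <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  data.frame(row = g$row, col = g$col, y0 = g$row * stride,
             x0 = g$col * stride, size = size)
}

#' Label one tile from the tissue and tumor masks
#'
#' The decision is total and deterministic: tiles with tissue fraction not
#' strictly above \code{minTissue} are \code{excluded}; otherwise a tumor
#' fraction at or above \code{minTumor} gives \code{tumor}; a tumor fraction
#' of exactly zero gives \code{non_tumor}; anything in between (an ambiguous
#' sliver of tumor) is \code{excluded}.
#'
#' @param tile one row of [tileGrid()] (list or data.frame row).
#' @param tissue,tumor binary H x W matrices covering the tile.
#' @param rules a [TileRules-class].
#' @return list with \code{tissueFraction}, \code{tumorFraction},
#'   \code{label} (\code{"tumor"}, \code{"non_tumor"} or \code{"excluded"})
#'   and \code{value} (1, 0, NA).
#' @export
labelTile <- function(tile, tissue, tumor, rules = tileRules()) {
  ys <- (tile$y0 + 1L):(tile$y0 + tile$size)
  xs <- (tile$x0 + 1L):(tile$x0 + tile$size)
  tf <- mean(tissue[ys, xs])
  uf <- mean(tumor[ys, xs])
  labelFromFractions(tf, uf, rules)
}

## rule kernel shared by labelTile and extractLabeledPatches
labelFromFractions <- function(tissueFraction, tumorFraction,
                               rules = tileRules()) {
  lab <- if (tissueFraction <= rules@minTissue) "excluded"
  else if (tumorFraction >= rules@minTumor) "tumor"
  else if (tumorFraction == 0 || !rules@nonTumorRequiresZero) "non_tumor"
  else "excluded"
  list(tissueFraction = tissueFraction, tumorFraction = tumorFraction,
       label = lab,
       value = switch(lab, tumor = 1L, non_tumor = 0L, NA_integer_))
}

#' Extract labelled tiles from an image with masks
#'
#' Applies [tileGrid()] and the labelling rules over a fixture (or any image
#' plus masks) and emits only the non-excluded tiles together with a manifest
#' recording geometry, fractions and label for every grid tile.
#'
#' @param bundle a [FixtureBundle-class], or \code{NULL} if \code{img},
#'   \code{tissue} and \code{tumor} are given directly.
#' @param rules a [TileRules-class].
#' @param size,stride grid geometry (defaults 224, no overlap).
#' @param img,tissue,tumor explicit inputs overriding \code{bundle}.
#' @param keepImages if FALSE only the manifest is returned (no pixel data).
#' @return list with \code{patches} (list of tile arrays for kept tiles, when
#'   \code{keepImages}), \code{labels} (0/1 per kept tile) and
#'   \code{manifest} (data.frame over all grid tiles: \code{row, col, y0,
#'   x0, tissue_fraction, tumor_fraction, label}). Warns when nothing
#'   survives.
#' @export
extractLabeledPatches <- function(bundle = NULL, rules = tileRules(),
                                  size = 224L, stride = size, img = NULL,
                                  tissue = NULL, tumor = NULL,
                                  keepImages = TRUE) {
  if (!is.null(bundle)) {
    img <- bundle@image; tissue <- bundle@tissueMask; tumor <- bundle@tumorMask
  }
  stopifnot(!is.null(tissue), !is.null(tumor))
  grid <- tileGrid(nrow(tissue), ncol(tissue), size, stride)
  recs <- vector("list", nrow(grid))
  patches <- list(); labels <- integer(0)
  for (i in seq_len(nrow(grid))) {
    tl <- grid[i, ]
    lb <- labelTile(tl, tissue, tumor, rules)
    recs[[i]] <- data.frame(row = tl$row, col = tl$col, y0 = tl$y0,
                            x0 = tl$x0,
                            tissue_fraction = lb$tissueFraction,
                            tumor_fraction = lb$tumorFraction,
                            label = lb$label)
    if (lb$label != "excluded") {
      labels <- c(labels, lb$value)
      if (keepImages && !is.null(img))
        patches[[length(patches) + 1L]] <-
          img[(tl$y0 + 1L):(tl$y0 + size), (tl$x0 + 1L):(tl$x0 + size), ,
              drop = FALSE]
    }
  }
  if (!length(labels)) warning("no tiles survive the labelling rules")
  list(patches = patches, labels = labels, manifest = do.call(rbind, recs))
}
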